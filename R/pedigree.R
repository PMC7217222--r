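#' Simulate a multi-generation random-mating pedigree
#'
#' Founders (generation 0) have unknown parents (coded 0). Each later
#' generation is produced by sampling a sire from the males and a dam from
#' the females of all earlier generations, mimicking a dairy population
#' where a limited sire team is mated widely across herds.
#'
#' @param n_founders number of founder animals (needs both sexes)
#' @param n_generations number of offspring generations (0 = founders only)
#' @param n_per_generation offspring produced per generation
#' @param prop_male probability an animal is male
#' @param n_sires size of the active sire team per generation (sampled
#'   from available males); `NULL` uses all males
#' @param seed optional RNG seed for reproducibility
#' @return data.frame `animal`, `sire`, `dam`, `sex` ("M"/"F"),
#'   `generation`, topologically ordered (parents precede offspring)
#' @export
simulate_pedigree <- function(n_founders, n_generations,
                              n_per_generation = n_founders,
                              prop_male = 0.5, n_sires = NULL, seed = NULL) {
  stopifnot(n_founders >= 2, n_generations >= 0, n_per_generation >= 1)
  if (!is.null(seed)) set.seed(seed)
  sex <- sample(c("M", "F"), n_founders, replace = TRUE,
                prob = c(prop_male, 1 - prop_male))
  if (n_generations > 0) {
    # guarantee both sexes among founders
    if (!any(sex == "M")) sex[sample.int(n_founders, 1)] <- "M"
    if (!any(sex == "F")) sex[sample.int(n_founders, 1)] <- "F"
  }
  ped <- data.frame(animal = seq_len(n_founders), sire = 0L, dam = 0L,
                    sex = sex, generation = 0L)
  for (g in seq_len(n_generations)) {
    males <- ped$animal[ped$sex == "M"]
    females <- ped$animal[ped$sex == "F"]
    if (length(males) == 0L || length(females) == 0L)
      stop("impossible mating structure: one sex absent in generation ",
           g - 1L)
    team <- if (is.null(n_sires)) males else
      males[sample.int(length(males), min(n_sires, length(males)))]
    n <- n_per_generation
    off <- data.frame(
      animal = max(ped$animal) + seq_len(n),
      sire = sample(team, n, replace = TRUE),
      dam = sample(females, n, replace = TRUE),
      sex = sample(c("M", "F"), n, replace = TRUE,
                   prob = c(prop_male, 1 - prop_male)),
      generation = g)
    ped <- rbind(ped, off)
  }
  ped
}

.check_ordered_pedigree <- function(ped) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  n <- nrow(ped)
  idx <- match(ped$animal, ped$animal)  # identity; ids may be arbitrary
  sire <- match(ped$sire, ped$animal)
  dam <- match(ped$dam, ped$animal)
  sire[ped$sire == 0] <- 0L
  dam[ped$dam == 0] <- 0L
  if (any(is.na(sire)) || any(is.na(dam)))
    stop("pedigree contains parents that never appear as animals")
  if (any(sire >= seq_len(n), na.rm = TRUE) ||
      any(dam >= seq_len(n), na.rm = TRUE))
    stop("pedigree is not ordered: a parent appears at or after its offspring")
  list(sire = sire, dam = dam)
}

#' Numerator relationship matrix (A) by the tabular method
#'
#' Builds the pedigree-expected additive relationship matrix row by row:
#' a_ij = (a_{j,sire(i)} + a_{j,dam(i)})/2 for j < i and
#' a_ii = 1 + a_{sire(i),dam(i)}/2, with unknown parents contributing 0.
#' Diagonals are 1 + F (F the inbreeding coefficient).
#'
#' @param ped ordered pedigree data.frame (`animal`, `sire`, `dam`;
#'   0 = unknown parent); parents must precede offspring
#' @return symmetric matrix with dimnames = animal ids
#' @export
a_matrix <- function(ped) {
  par <- .check_ordered_pedigree(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- par$sire[i]; d <- par$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (s > 0) A[j, s] else 0) + (if (d > 0) A[j, d] else 0))
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' @inheritParams a_matrix
#' @return numeric vector F (diag(A) - 1), named by animal id
#' @export
inbreeding <- function(ped) {
  diag(a_matrix(ped)) - 1
}
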