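#' Build a pedigree from animal/sire/dam records
#'
#' Validates and topologically sorts a set of pedigree records so that every
#' parent precedes its offspring. Parents that are referenced but have no row
#' of their own are materialised as founders with unknown birth year and a
#' sex inferred from the slot they occupy (sires male, dams female).
#'
#' @param x A data frame with columns `animal`, `sire`, `dam` and optionally
#'   `birth_year` and `sex`. Unknown parents are encoded as `NA`, `""` or
#'   `"0"`. `sex` uses `"M"`, `"F"` or `"U"` (unknown).
#' @return A tibble of class `pedigree` with columns `animal`, `sire`, `dam`
#'   (character, `NA` = unknown), `birth_year` (integer) and `sex`, ordered
#'   so that parents come before offspring.
#' @examples
#' ped <- pedigree(data.frame(
#'   animal = c("calf", "bull", "cow"),
#'   sire   = c("bull", NA, NA),
#'   dam    = c("cow", NA, NA),
#'   birth_year = c(2001L, 1998L, 1997L),
#'   sex = c("F", "M", "F")
#' ))
#' @export
pedigree <- function(x) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("animal", "sire", "dam") %in% names(x)))
  norm_id <- function(v) {
    v <- as.character(v)
    v[!is.na(v) & (v == "0" | trimws(v) == "")] <- NA_character_
    v
  }
  x$animal <- as.character(x$animal)
  x$sire <- norm_id(x$sire)
  x$dam <- norm_id(x$dam)
  if (anyNA(x$animal) || any(trimws(x$animal) == "")) {
    stop("missing animal identifier in pedigree records", call. = FALSE)
  }
  if (anyDuplicated(x$animal)) {
    dup <- unique(x$animal[duplicated(x$animal)])
    stop("duplicate animal_id in pedigree: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (!"birth_year" %in% names(x)) x$birth_year <- NA_integer_
  x$birth_year <- as.integer(x$birth_year)
  if (!"sex" %in% names(x)) x$sex <- "U"
  x$sex <- toupper(as.character(x$sex))
  x$sex[is.na(x$sex) | !(x$sex %in% c("M", "F"))] <- "U"

  # materialise referenced-but-absent parents as founders
  ghosts_s <- setdiff(stats::na.omit(x$sire), x$animal)
  ghosts_d <- setdiff(stats::na.omit(x$dam), x$animal)
  if (length(ghosts_s) || length(ghosts_d)) {
    ghosts <- tibble::tibble(
      animal = c(ghosts_s, setdiff(ghosts_d, ghosts_s)),
      sire = NA_character_, dam = NA_character_,
      birth_year = NA_integer_,
      sex = c(rep("M", length(ghosts_s)),
              rep("F", length(setdiff(ghosts_d, ghosts_s))))
    )
    x <- dplyr::bind_rows(x[, names(ghosts)], ghosts[, names(ghosts)])
  }
  x <- x[, c("animal", "sire", "dam", "birth_year", "sex")]

  ord <- ped_topological_order(x$animal, x$sire, x$dam)
  out <- x[ord, ]
  class(out) <- c("pedigree", class(tibble::tibble()))
  out
}

#' @export
print.pedigree <- function(x, ...) {
  n_founder <- sum(is.na(x$sire) & is.na(x$dam))
  yrs <- if (all(is.na(x$birth_year))) c("?", "?") else {
    range(x$birth_year, na.rm = TRUE)
  }
  cat(sprintf("<pedigree> %d animals (%d founders), birth years %s-%s\n",
              nrow(x), n_founder, yrs[1], yrs[2]))
  NextMethod()
}

# Kahn topological sort; fatal on cycles, reporting the offending ids.
ped_topological_order <- function(animal, sire, dam) {
  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    stuck <- animal[setdiff(seq_len(n), ord)]
    stop("pedigree contains a cycle involving: ",
         paste(utils::head(stuck, 10), collapse = " -> "), call. = FALSE)
  }
  ord
}

#' Read a pedigree file
#'
#' Reads a comma- or tab-delimited pedigree file with header
#' `animal,sire,dam,birth_year,sex` (the last two optional). Unknown parents
#' may be encoded as `0` or left empty. Rows are re-ordered topologically.
#'
#' @param path Path to the delimited text file.
#' @return A [pedigree] tibble.
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  x <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  pedigree(x)
}

#' Write a per-animal inbreeding table as TSV
#'
#' @param f Tibble with columns `animal` and `F` as returned by
#'   [inbreeding_ml()].
#' @param path Output path.
#' @export
write_inbreeding <- function(f, path) {
  readr::write_tsv(f, path)
  invisible(path)
}

ped_parent_idx <- function(ped) {
  list(s = match(ped$sire, ped$animal), d = match(ped$dam, ped$animal))
}

#' Pedigree completeness index
#'
#' Completeness over the first `d` ancestral generations,
#' `C = (1/d) * sum_{i=1..d} a_i`, where `a_i` is the proportion of the
#' `2^i` ancestor slots in generation `i` that are occupied by known
#' animals. An ancestor only counts as known when every intermediate
#' ancestor on the path to it is known (path blocking).
#'
#' @param ped A [pedigree].
#' @param animals Character vector of animal ids (default: all).
#' @param d Number of generations (>= 1).
#' @return A tibble with columns `animal` and `completeness`.
#' @export
pedigree_completeness <- function(ped, animals = ped$animal, d) {
  if (length(d) != 1L || is.na(d) || d < 1) {
    stop("d must be a single integer >= 1", call. = FALSE)
  }
  d <- as.integer(d)
  idx <- match(animals, ped$animal)
  if (anyNA(idx)) {
    stop("unknown animal id(s): ",
         paste(animals[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  pi <- ped_parent_idx(ped)
  comp_one <- function(i) {
    gen <- i
    a <- numeric(d)
    for (g in seq_len(d)) {
      gen <- c(pi$s[gen], pi$d[gen])
      gen <- gen[!is.na(gen)]
      a[g] <- length(gen) / 2^g
      if (!length(gen)) break
    }
    mean(a)
  }
  tibble::tibble(animal = animals,
                 completeness = vapply(idx, comp_one, numeric(1)))
}

#' Pedigree inbreeding coefficients (Meuwissen-Luo)
#'
#' Computes the inbreeding coefficient `F = diag(A) - 1` of the numerator
#' relationship matrix for every animal without materialising `A`, using the
#' Meuwissen-Luo ancestor-tracing algorithm: processing animals in
#' topological order, `A_ii = sum_j L_ij^2 m_j` where `L` traces gamete
#' contributions through the ancestors of `i` and `m_j` is the Mendelian
#' sampling variance of `j` given its parents' inbreeding. Unknown parents
#' contribute relationship 0 (founders have `F = 0`).
#'
#' Animals sharing both parents share `F`, which is exploited with a cache.
#'
#' @param ped A [pedigree].
#' @return A tibble with columns `animal` and `F` (proportion in \[0, 1\]).
#' @export
inbreeding_ml <- function(ped) {
  pi <- ped_parent_idx(ped)
  n <- nrow(ped)
  s <- pi$s
  d <- pi$d
  f <- numeric(n)
  m <- numeric(n) # Mendelian sampling variance coefficients
  cache <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    if (is.na(s[i]) && is.na(d[i])) {
      f[i] <- 0
      m[i] <- 1
      next
    }
    key <- paste(s[i], d[i])
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) {
      f[i] <- hit
    } else if (is.na(s[i]) || is.na(d[i])) {
      f[i] <- 0 # one unknown parent: parents cannot be related through it
    } else {
      # A_ii = sum over ancestors j of L_j^2 * m_j; F = A_ii - 1
      L <- numeric(i)
      L[i] <- 1
      aii <- 0
      for (j in i:1) {
        lj <- L[j]
        if (lj == 0) next
        mj <- if (j < i) m[j] else 0.5 - 0.25 * (f[s[i]] + f[d[i]])
        aii <- aii + lj * lj * mj
        if (!is.na(s[j])) L[s[j]] <- L[s[j]] + 0.5 * lj
        if (!is.na(d[j])) L[d[j]] <- L[d[j]] + 0.5 * lj
      }
      f[i] <- aii - 1
    }
    assign(key, f[i], envir = cache)
    m[i] <- mendelian_variance(f, s[i], d[i])
  }
  tibble::tibble(animal = ped$animal, F = f)
}

# Mendelian sampling variance coefficient given parental inbreeding
mendelian_variance <- function(f, si, di) {
  if (is.na(si) && is.na(di)) 1
  else if (is.na(si)) 0.75 - 0.25 * f[di]
  else if (is.na(di)) 0.75 - 0.25 * f[si]
  else 0.5 - 0.25 * (f[si] + f[di])
}

#' Dense numerator relationship matrix by the tabular method
#'
#' Recursive tabular construction of the additive relationship matrix `A`:
#' `A_ii = 1 + 0.5 A_{sire,dam}` and `A_ij = 0.5 (A_{j,sire(i)} +
#' A_{j,dam(i)})` for `j` preceding `i`, with unknown parents contributing
#' zero. Intended as a desk-scale oracle for [inbreeding_ml()] and
#' [a_inverse()]; refuses pedigrees above `max_animals`.
#'
#' @param ped A [pedigree].
#' @param max_animals Dense-size guard (default 2000).
#' @return Dense symmetric matrix with dimnames = animal ids.
#' @export
relationship_matrix_tabular <- function(ped, max_animals = 2000) {
  n <- nrow(ped)
  if (n > max_animals) {
    stop("pedigree has ", n, " animals; tabular method is dense and guarded at ",
         max_animals, call. = FALSE)
  }
  pi <- ped_parent_idx(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    si <- pi$s[i]
    di <- pi$d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(si)) row <- row + 0.5 * A[si, j]
      if (!is.na(di)) row <- row + 0.5 * A[di, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) 0.5 * A[si, di] else 0
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules accounting for inbreeding: each animal contributes
#' `k = 1/m_i` (the reciprocal of its Mendelian sampling variance, computed
#' from parental inbreeding coefficients) at `(i,i)`, `-k/2` at
#' `(i, parent)` and `k/4` at parent-parent positions.
#'
#' @param ped A [pedigree].
#' @param f Optional inbreeding table from [inbreeding_ml()]; computed if
#'   missing. Must cover every animal in `ped`.
#' @return A sparse symmetric `Matrix::dsCMatrix` with dimnames = animal
#'   ids, plus attribute `log_det_A` (the log-determinant of `A` itself,
#'   `sum(log m_i)`).
#' @export
a_inverse <- function(ped, f = NULL) {
  if (is.null(f)) f <- inbreeding_ml(ped)
  fv <- f$F[match(ped$animal, f$animal)]
  if (anyNA(fv)) {
    stop("inbreeding table is missing animals: ",
         paste(utils::head(ped$animal[is.na(fv)], 5), collapse = ", "),
         call. = FALSE)
  }
  pi <- ped_parent_idx(ped)
  n <- nrow(ped)
  s <- pi$s
  d <- pi$d
  fs <- ifelse(is.na(s), 0, fv[ifelse(is.na(s), 1L, s)])
  fd <- ifelse(is.na(d), 0, fv[ifelse(is.na(d), 1L, d)])
  m <- ifelse(!is.na(s) & !is.na(d), 0.5 - 0.25 * (fs + fd),
       ifelse(!is.na(s), 0.75 - 0.25 * fs,
       ifelse(!is.na(d), 0.75 - 0.25 * fd, 1)))
  k <- 1 / m
  ii <- seq_len(n)
  ti <- ii; tj <- ii; tx <- k
  add <- function(i, j, x) {
    ti <<- c(ti, i); tj <<- c(tj, j); tx <<- c(tx, x)
  }
  hs <- !is.na(s)
  hd <- !is.na(d)
  add(ii[hs], s[hs], -k[hs] / 2)
  add(s[hs], ii[hs], -k[hs] / 2)
  add(ii[hd], d[hd], -k[hd] / 2)
  add(d[hd], ii[hd], -k[hd] / 2)
  add(s[hs], s[hs], k[hs] / 4)
  add(d[hd], d[hd], k[hd] / 4)
  both <- hs & hd
  add(s[both], d[both], k[both] / 4)
  add(d[both], s[both], k[both] / 4)
  ai <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n),
                             dimnames = list(ped$animal, ped$animal),
                             symmetric = FALSE)
  ai <- Matrix::forceSymmetric(ai)
  attr(ai, "log_det_A") <- sum(log(m))
  ai
}

#' Select phenotype-eligible cows
#'
#' Females born in or after `min_birth_year` whose pedigree is complete
#' over the first `complete_generations` generations (completeness index
#' exactly 1).
#'
#' @param ped A [pedigree].
#' @param min_birth_year Earliest admissible birth year (default 1995).
#' @param complete_generations Generations that must be fully known
#'   (default 2).
#' @return Character vector of animal ids.
#' @export
filter_cows <- function(ped, min_birth_year = 1995, complete_generations = 2) {
  cand <- ped$animal[ped$sex == "F" & !is.na(ped$birth_year) &
                       ped$birth_year >= min_birth_year]
  if (!length(cand)) return(character(0))
  comp <- pedigree_completeness(ped, cand, d = complete_generations)
  comp$animal[comp$completeness >= 1 - 1e-12]
}

#' Trend of inbreeding on birth year
#'
#' Ordinary least-squares regression of the pedigree inbreeding coefficient
#' on birth year over animals born within `year_range`.
#'
#' @param f Inbreeding table (`animal`, `F`).
#' @param ped A [pedigree].
#' @param year_range Length-2 numeric, inclusive bounds.
#' @return One-row tibble: `slope` (F proportion per year), `se`,
#'   `n_animals`, `p_value`.
#' @export
inbreeding_trend <- function(f, ped, year_range = range(ped$birth_year, na.rm = TRUE)) {
  dat <- dplyr::inner_join(f, ped[, c("animal", "birth_year")], by = "animal")
  dat <- dat[!is.na(dat$birth_year) &
               dat$birth_year >= year_range[1] & dat$birth_year <= year_range[2], ]
  if (length(unique(dat$birth_year)) < 2) {
    stop("need at least two distinct birth years in range", call. = FALSE)
  }
  fit <- stats::lm(F ~ birth_year, data = dat)
  # suppress the "essentially perfect fit" warning for noiseless inputs
  cf <- suppressWarnings(summary(fit))$coefficients
  tibble::tibble(slope = cf["birth_year", 1], se = cf["birth_year", 2],
                 n_animals = nrow(dat), p_value = cf["birth_year", 4])
}
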