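# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

# Random valid pedigree: parents always precede offspring, some unknown.
random_pedigree <- function(n, n_founder = max(5L, n %/% 10L),
                            p_known = 0.9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sire <- dam <- rep(NA_character_, n)
  for (i in seq.int(n_founder + 1L, n)) {
    prev <- seq_len(i - 1L)
    m <- prev[sex[prev] == "M"]
    f <- prev[sex[prev] == "F"]
    if (length(m) && stats::runif(1) < p_known) sire[i] <- as.character(sample(m, 1))
    if (length(f) && stats::runif(1) < p_known) dam[i] <- as.character(sample(f, 1))
  }
  pedigree(tibble::tibble(animal = as.character(seq_len(n)), sire = sire,
                          dam = dam,
                          birth_year = 2000L + (seq_len(n) %/% 25L),
                          sex = sex))
}

# Trio + full-sib + half-sib textbook pedigree.
textbook_pedigree <- function() {
  pedigree(data.frame(
    animal = c("s", "d", "d2", "fs1", "fs2", "hs", "fsoff", "hsoff", "po"),
    sire   = c(NA, NA, NA, "s", "s", "s", "fs1", "hs", "s"),
    dam    = c(NA, NA, NA, "d", "d", "d2", "fs2", "fs2", "fs2"),
    birth_year = c(1990, 1990, 1990, 1995, 1995, 1995, 2000, 2000, 2000),
    sex    = c("M", "F", "F", "M", "F", "M", "F", "F", "F")
  ))
}

# Small genotype matrix with explicit codes (animals x SNPs), one or two
# chromosomes.
toy_geno <- function(codes, chr = NULL, pos = NULL) {
  n_snp <- ncol(codes)
  if (is.null(chr)) chr <- rep("1", n_snp)
  if (is.null(pos)) {
    pos <- unlist(lapply(split(seq_len(n_snp), chr)[unique(chr)], seq_along))
    pos <- pos * 1000L
  }
  if (is.null(rownames(codes))) {
    rownames(codes) <- sprintf("a%02d", seq_len(nrow(codes)))
  }
  geno_matrix(codes, tibble::tibble(
    snp_id = sprintf("snp%04d", seq_len(n_snp)), chr = as.character(chr),
    pos_bp = as.integer(pos)))
}

# Independent linear-scan ROH oracle: examines every start position and
# extends while homozygous; no reuse of the rle-based implementation.
brute_force_roh <- function(hom) {
  runs <- list()
  i <- 1L
  n <- length(hom)
  while (i <= n) {
    if (isTRUE(hom[i])) {
      j <- i
      while (j < n && isTRUE(hom[j + 1L])) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(start = i, end = j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  runs
}

# Quadratic all-pairs ROH oracle for small strings: a run is any maximal
# (start, end) with all positions homozygous.
quadratic_roh <- function(hom) {
  n <- length(hom)
  runs <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (all(hom[s:e]) &&
          (s == 1L || !isTRUE(hom[s - 1L])) &&
          (e == n || !isTRUE(hom[e + 1L]))) {
        runs[[length(runs) + 1L]] <- c(start = s, end = e)
      }
    }
  }
  unique(runs)
}

# Phenotypes for unrelated cows with known fixed effects (for model tests).
simple_phen <- function(n_cows, k = 3, seed = 1, sigma = 1) {
  set.seed(seed)
  cows <- sprintf("c%04d", seq_len(n_cows))
  ped <- pedigree(data.frame(animal = cows, sire = NA, dam = NA,
                             birth_year = 2000, sex = "F"))
  dat <- tibble::tibble(
    cow = rep(cows, each = k),
    hys = sample(1:6, n_cows * k, replace = TRUE),
    parity = rep(seq_len(k), n_cows),
    month = sample(1:12, n_cows * k, replace = TRUE),
    age_fc = round(stats::rnorm(n_cows * k, 26, 2), 2))
  dat$value <- 50 + 0.4 * dat$age_fc + (1:6 / 4)[dat$hys] +
    stats::rnorm(n_cows * k, 0, sigma)
  list(ped = ped, phen = dat, cows = cows)
}
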