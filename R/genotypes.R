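#' Construct a genotype matrix object
#'
#' Couples an animals-by-SNPs matrix of allele counts (0/1/2, `NA` =
#' missing; homozygotes are 2 or 0, heterozygotes 1) with a SNP map.
#' SNPs are sorted by (chromosome, position) and positions must be strictly
#' increasing within a chromosome.
#'
#' @param codes Integer/numeric matrix, animals in rows (rownames = animal
#'   ids), SNPs in columns.
#' @param map Data frame with columns `snp_id`, `chr`, `pos_bp` matching the
#'   columns of `codes`.
#' @return An object of class `geno_matrix`: a list with elements `codes`
#'   and `map` (tibble).
#' @export
geno_matrix <- function(codes, map) {
  map <- tibble::as_tibble(map)
  stopifnot(all(c("snp_id", "chr", "pos_bp") %in% names(map)),
            ncol(codes) == nrow(map))
  if (is.null(rownames(codes))) {
    stop("codes must have animal ids as rownames", call. = FALSE)
  }
  map$snp_id <- as.character(map$snp_id)
  map$chr <- as.character(map$chr)
  map$pos_bp <- as.integer(map$pos_bp)
  bad <- !(codes %in% c(0, 1, 2) | is.na(codes))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  storage.mode(codes) <- "integer"
  ord <- order(chr_rank(map$chr), map$pos_bp)
  map <- map[ord, ]
  codes <- codes[, ord, drop = FALSE]
  colnames(codes) <- map$snp_id
  dup <- unlist(tapply(map$pos_bp, map$chr, function(p) any(diff(p) <= 0)))
  if (any(dup)) {
    stop("positions must be strictly increasing within chromosome: ",
         paste(names(dup)[dup], collapse = ", "), call. = FALSE)
  }
  structure(list(codes = codes, map = map), class = "geno_matrix")
}

# numeric chromosomes first in numeric order, then lexicographic (X, Y, MT)
chr_rank <- function(chr) {
  num <- suppressWarnings(as.numeric(chr))
  rank <- ifelse(is.na(num), 1e6 + as.integer(factor(chr)), num)
  rank
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d animals x %d SNPs on %d chromosome(s); %.2f%% missing\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$map$chr)),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' Read PLINK PED/MAP text genotypes
#'
#' Reads a PLINK text pair. Genotypes are recoded biallelically with code 2
#' counting the A1 allele, where A1 is the first non-missing allele
#' encountered at each SNP in the PED file. `0 0` (or a half-missing call)
#' becomes `NA`. More than two alleles at a SNP is an error.
#'
#' @param path_ped PED file (FID IID PAT MAT SEX PHENO + 2 columns/SNP).
#' @param path_map MAP file (chr, snp_id, cM, bp) or (chr, snp_id, bp).
#' @return A [geno_matrix].
#' @export
read_genotypes <- function(path_ped, path_map) {
  map_raw <- utils::read.table(path_map, header = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) == 4) {
    map <- tibble::tibble(snp_id = map_raw[[2]], chr = map_raw[[1]],
                          pos_bp = as.integer(map_raw[[4]]))
  } else if (ncol(map_raw) == 3) {
    map <- tibble::tibble(snp_id = map_raw[[2]], chr = map_raw[[1]],
                          pos_bp = as.integer(map_raw[[3]]))
  } else {
    stop("MAP file must have 3 or 4 columns", call. = FALSE)
  }
  ped_raw <- utils::read.table(path_ped, header = FALSE,
                               colClasses = "character")
  n_snp <- nrow(map)
  if (ncol(ped_raw) != 6 + 2 * n_snp) {
    stop("PED/MAP mismatch: PED implies ", (ncol(ped_raw) - 6) / 2,
         " SNPs, MAP lists ", n_snp, call. = FALSE)
  }
  ids <- ped_raw[[2]]
  codes <- matrix(NA_integer_, nrow(ped_raw), n_snp,
                  dimnames = list(ids, map$snp_id))
  for (m in seq_len(n_snp)) {
    a <- ped_raw[[6 + 2 * m - 1]]
    b <- ped_raw[[6 + 2 * m]]
    miss <- a == "0" | b == "0"
    alleles <- unique(c(a[!miss], b[!miss]))
    if (length(alleles) > 2) {
      stop("SNP ", map$snp_id[m], " has more than two alleles: ",
           paste(alleles, collapse = "/"), call. = FALSE)
    }
    if (length(alleles) == 0) next
    a1 <- alleles[1]
    codes[, m] <- (a == a1) + (b == a1)
    codes[miss, m] <- NA_integer_
  }
  geno_matrix(codes, map)
}

#' Read the matrix-TSV genotype dialect
#'
#' Header row of SNP ids, then one row per animal: animal id followed by
#' codes 0/1/2 with `NA` for missing. A SNP map (file or data frame with
#' `snp_id`, `chr`, `pos_bp`) supplies positions.
#'
#' @param path TSV path.
#' @param map Data frame or path to a TSV with columns `snp_id`, `chr`,
#'   `pos_bp`.
#' @return A [geno_matrix].
#' @export
read_geno_tsv <- function(path, map) {
  if (is.character(map)) {
    map <- readr::read_tsv(map, show_col_types = FALSE, progress = FALSE)
  }
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  codes <- as.matrix(x[, -1, drop = FALSE])
  rownames(codes) <- as.character(x[[1]])
  map <- map[match(colnames(codes), as.character(map$snp_id)), ]
  geno_matrix(codes, map)
}

#' Write a genotype matrix as TSV (+ map)
#'
#' @param g A [geno_matrix].
#' @param path Genotype TSV path.
#' @param path_map Map TSV path (default: `path` with `.map.tsv`).
#' @export
write_geno_tsv <- function(g, path, path_map = sub("\\.tsv$", ".map.tsv", path)) {
  df <- tibble::as_tibble(g$codes, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(animal = rownames(g$codes)), df)
  readr::write_tsv(df, path)
  readr::write_tsv(g$map, path_map)
  invisible(c(path, path_map))
}

#' Allele frequencies from a genotype matrix
#'
#' Frequency of the allele counted by code 2, `p = mean(code)/2` over
#' non-missing genotypes of the reference animals (by default every
#' genotyped animal, which may include reference males in addition to the
#' phenotyped cows).
#'
#' @param g A [geno_matrix].
#' @param reference_ids Optional subset of animal ids over which to count.
#' @return Tibble with `snp_id`, `p`, `n_obs` and flags `monomorphic`
#'   (p is 0 or 1) and `all_missing`.
#' @export
allele_frequencies <- function(g, reference_ids = NULL) {
  codes <- g$codes
  if (!is.null(reference_ids)) {
    missing_ids <- setdiff(reference_ids, rownames(codes))
    if (length(missing_ids)) {
      stop("reference ids not genotyped: ",
           paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
    }
    codes <- codes[reference_ids, , drop = FALSE]
  }
  n_obs <- colSums(!is.na(codes))
  p <- colMeans(codes, na.rm = TRUE) / 2
  p[n_obs == 0] <- NA_real_
  tibble::tibble(snp_id = g$map$snp_id, p = unname(p), n_obs = unname(n_obs),
                 monomorphic = !is.na(p) & (p <= 0 | p >= 1),
                 all_missing = n_obs == 0)
}

#' Genomic self-relationship inbreeding coefficient (GRM_F)
#'
#' Per-animal inbreeding from the diagonal of the genomic relationship
#' matrix. The default `"yang"` variant averages the per-SNP term
#' `(x^2 - (1 + 2p) x + 2 p^2) / (2 p (1 - p))` over usable SNPs, which is
#' the GRM self-relationship minus 1 (0 in expectation at Hardy-Weinberg
#' base frequencies; -1 for a fully heterozygous animal). The
#' `"vanraden_diag"` variant is `sum (x - 2p)^2 / (2 sum p(1-p)) - 1`.
#' Monomorphic SNPs and missing genotypes are dropped from both the sum and
#' its denominator.
#'
#' @param g A [geno_matrix].
#' @param p Allele frequencies from [allele_frequencies()]; computed from
#'   `g` if omitted.
#' @param animals Animal ids (default all).
#' @param variant `"yang"` (default) or `"vanraden_diag"`.
#' @return Tibble with `animal`, `grm_f`, `n_snps_used`.
#' @export
grm_self_relationship <- function(g, p = allele_frequencies(g), animals = NULL,
                                  variant = c("yang", "vanraden_diag")) {
  variant <- match.arg(variant)
  codes <- g$codes
  if (!is.null(animals)) codes <- codes[animals, , drop = FALSE]
  pv <- p$p[match(g$map$snp_id, p$snp_id)]
  usable <- !is.na(pv) & pv > 0 & pv < 1
  if (!any(usable)) stop("no polymorphic SNP with defined frequency", call. = FALSE)
  x <- codes[, usable, drop = FALSE]
  pv <- pv[usable]
  obs <- !is.na(x)
  n_used <- rowSums(obs)
  if (any(n_used == 0)) {
    stop("animal(s) with no usable genotype: ",
         paste(utils::head(rownames(x)[n_used == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  if (variant == "yang") {
    het <- 2 * pv * (1 - pv)
    term <- x * x - sweep(x, 2, 1 + 2 * pv, "*")
    term <- sweep(term, 2, 2 * pv^2, "+")
    term <- sweep(term, 2, het, "/")
    term[!obs] <- 0
    grm_f <- rowSums(term) / n_used
  } else {
    dev <- sweep(x, 2, 2 * pv, "-")^2
    dev[!obs] <- 0
    hetm <- matrix(2 * pv * (1 - pv), nrow(x), length(pv), byrow = TRUE)
    hetm[!obs] <- 0
    grm_f <- rowSums(dev) / rowSums(hetm) - 1
  }
  tibble::tibble(animal = rownames(x), grm_f = unname(grm_f),
                 n_snps_used = unname(n_used))
}

#' Proportion of homozygous SNP genotypes
#'
#' Fraction of an animal's non-missing genotypes that are homozygous
#' (code 0 or 2). Monomorphic SNPs are retained.
#'
#' @param g A [geno_matrix].
#' @param animals Animal ids (default all).
#' @return Tibble with `animal`, `homozygosity`, `n_obs`.
#' @export
homozygosity_proportion <- function(g, animals = NULL) {
  codes <- g$codes
  if (!is.null(animals)) codes <- codes[animals, , drop = FALSE]
  n_obs <- rowSums(!is.na(codes))
  if (any(n_obs == 0)) {
    stop("animal(s) with all genotypes missing: ",
         paste(utils::head(rownames(codes)[n_obs == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  hom <- rowSums(codes != 1, na.rm = TRUE)
  tibble::tibble(animal = rownames(codes), homozygosity = unname(hom / n_obs),
                 n_obs = unname(n_obs))
}

#' Detect runs of homozygosity
#'
#' Maximal stretches of consecutive homozygous genotypes within each
#' chromosome. A heterozygote, a missing call or a chromosome end
#' terminates a run; runs contain no missing calls. `span_bp` is the
#' distance between the first and last SNP of the run.
#'
#' @param g A [geno_matrix].
#' @param animals Animal ids (default all).
#' @return Tibble of class `roh_set`: `animal`, `chr`, `start_idx`,
#'   `end_idx` (global column indices, inclusive), `n_snps`, `start_bp`,
#'   `end_bp`, `span_bp`.
#' @export
detect_roh <- function(g, animals = NULL) {
  codes <- g$codes
  if (!is.null(animals)) codes <- codes[animals, , drop = FALSE]
  map <- g$map
  chr_levels <- unique(map$chr)
  out <- vector("list", nrow(codes) * length(chr_levels))
  k <- 0L
  for (a in seq_len(nrow(codes))) {
    for (ch in chr_levels) {
      cols <- which(map$chr == ch)
      hom <- codes[a, cols] != 1L
      hom[is.na(hom)] <- FALSE
      r <- rle(hom)
      if (!any(r$values)) next
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values
      k <- k + 1L
      s <- cols[starts[keep]]
      e <- cols[ends[keep]]
      out[[k]] <- tibble::tibble(
        animal = rownames(codes)[a], chr = ch,
        start_idx = s, end_idx = e, n_snps = e - s + 1L,
        start_bp = map$pos_bp[s], end_bp = map$pos_bp[e],
        span_bp = map$pos_bp[e] - map$pos_bp[s]
      )
    }
  }
  res <- if (k) dplyr::bind_rows(out[seq_len(k)]) else
    tibble::tibble(animal = character(), chr = character(),
                   start_idx = integer(), end_idx = integer(),
                   n_snps = integer(), start_bp = integer(),
                   end_bp = integer(), span_bp = integer())
  class(res) <- c("roh_set", class(res))
  res
}

#' Write runs of homozygosity as BED-like TSV
#'
#' Columns: animal, chromosome, start_bp, end_bp (inclusive positions of
#' the first and last SNP in the run), n_snps.
#'
#' @param roh A `roh_set` from [detect_roh()].
#' @param path Output path.
#' @export
write_roh <- function(roh, path) {
  readr::write_tsv(roh[, c("animal", "chr", "start_bp", "end_bp", "n_snps")],
                   path)
  invisible(path)
}

#' ROH-based inbreeding coefficient
#'
#' Proportion of SNP positions lying inside a run of homozygosity of at
#' least `n` SNPs, out of all `nsnp_total` SNP positions.
#'
#' @param roh A `roh_set` from [detect_roh()].
#' @param nsnp_total Total number of SNP positions on the array.
#' @param n Minimum run length in SNPs (>= 1); may be a vector.
#' @return Tibble with `animal`, `n`, `roh_f`; animals present in `roh`
#'   with no qualifying run get 0.
#' @export
roh_f <- function(roh, nsnp_total, n) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  animals <- unique(roh$animal)
  grid <- tidyr::expand_grid(animal = animals, n = as.integer(n))
  sums <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    sel <- roh$animal == grid$animal[i] & roh$n_snps >= grid$n[i]
    sum(roh$n_snps[sel])
  })
  grid$roh_f <- sums / nsnp_total
  grid
}

#' Per-position ROH indicator
#'
#' For each SNP position and animal, whether a run of homozygosity of at
#' least `n` SNPs is present at that position. Two readings are supported:
#' `"window_start"` (the default scan covariate) marks position `i` when
#' the window of `n` SNPs starting at `i` is entirely homozygous;
#' `"covering"` marks `i` when it lies inside any maximal run of at least
#' `n` SNPs. In `window_start` mode, positions whose window would leave the
#' chromosome are `NA` (not testable).
#'
#' @param g A [geno_matrix].
#' @param n Minimum run length in SNPs.
#' @param mode `"window_start"` or `"covering"`.
#' @param animals Animal ids (default all).
#' @return Integer matrix (animals x SNPs) of 0/1 with `NA` for untestable
#'   window-start positions.
#' @export
roh_indicator <- function(g, n, mode = c("window_start", "covering"),
                          animals = NULL) {
  mode <- match.arg(mode)
  codes <- g$codes
  if (!is.null(animals)) codes <- codes[animals, , drop = FALSE]
  map <- g$map
  ind <- matrix(NA_integer_, nrow(codes), ncol(codes),
                dimnames = dimnames(codes))
  if (mode == "window_start") {
    hom <- (codes != 1L)
    hom[is.na(hom)] <- FALSE
    for (ch in unique(map$chr)) {
      cols <- which(map$chr == ch)
      L <- length(cols)
      if (L < n) next
      cs <- cbind(0, t(apply(hom[, cols, drop = FALSE], 1, cumsum)))
      win <- cs[, (n + 1):(L + 1), drop = FALSE] - cs[, 1:(L - n + 1), drop = FALSE]
      ind[, cols[1:(L - n + 1)]] <- (win == n) + 0L
    }
  } else {
    ind[] <- 0L
    runs <- detect_roh(geno_matrix(codes, map))
    runs <- runs[runs$n_snps >= n, ]
    for (i in seq_len(nrow(runs))) {
      ind[runs$animal[i], runs$start_idx[i]:runs$end_idx[i]] <- 1L
    }
  }
  ind
}

#' Opposing homozygotes between two animals
#'
#' Counts SNPs where one animal is homozygous for one allele (code 0) and
#' the other homozygous for the alternative (code 2); missing genotypes are
#' skipped. A putative parent-offspring pair with more than `threshold`
#' opposing homozygotes is flagged incompatible.
#'
#' @param g A [geno_matrix].
#' @param child,parent Animal ids.
#' @param threshold Incompatibility threshold (default 20).
#' @return One-row tibble: `child`, `parent`, `n_opposing`, `n_compared`,
#'   `incompatible`.
#' @export
opposing_homozygotes <- function(g, child, parent, threshold = 20) {
  a <- g$codes[child, ]
  b <- g$codes[parent, ]
  ok <- !is.na(a) & !is.na(b)
  n_opp <- sum((a[ok] == 0L & b[ok] == 2L) | (a[ok] == 2L & b[ok] == 0L))
  tibble::tibble(child = child, parent = parent,
                 n_opposing = n_opp, n_compared = sum(ok),
                 incompatible = n_opp > threshold)
}

#' Combined per-animal inbreeding measures
#'
#' Assembles pedigree inbreeding, the GRM self-relationship, SNP
#' homozygosity and ROH-based inbreeding over a grid of minimum run
#' lengths into one table.
#'
#' @param ped A [pedigree].
#' @param g A [geno_matrix]; animals must appear in `ped`.
#' @param n_grid Minimum ROH lengths in SNPs (default `c(1, seq(5, 100, 5))`).
#' @param p Allele frequencies (default: computed over all animals in `g`).
#' @param grm_variant Passed to [grm_self_relationship()].
#' @return Tibble with one row per genotyped animal: `animal`, `f_ped`,
#'   `grm_f`, `homozygosity`, and one `roh_f_<n>` column per grid value.
#' @export
inbreeding_measures <- function(ped, g, n_grid = c(1L, seq(5L, 100L, 5L)),
                                p = allele_frequencies(g),
                                grm_variant = "yang") {
  fped <- inbreeding_ml(ped)
  grmf <- grm_self_relationship(g, p, variant = grm_variant)
  hom <- homozygosity_proportion(g)
  roh <- detect_roh(g)
  rohf <- roh_f(roh, ncol(g$codes), n_grid)
  rohw <- tidyr::pivot_wider(rohf, names_from = "n", values_from = "roh_f",
                             names_prefix = "roh_f_")
  out <- tibble::tibble(animal = rownames(g$codes))
  out <- dplyr::left_join(out, fped, by = "animal")
  out <- dplyr::rename(out, f_ped = "F")
  out <- dplyr::left_join(out, grmf[, c("animal", "grm_f")], by = "animal")
  out <- dplyr::left_join(out, hom[, c("animal", "homozygosity")], by = "animal")
  out <- dplyr::left_join(out, rohw, by = "animal")
  roh_cols <- grep("^roh_f_", names(out))
  out[roh_cols][is.na(out[roh_cols])] <- 0 # genotyped animal with no run
  out
}

#' Correlations between inbreeding measures
#'
#' Pearson correlations across animals for every pair of measures in a
#' table produced by [inbreeding_measures()] (or any per-animal table of
#' numeric measures). Constant measures give `NA` with a warning.
#'
#' @param m Per-animal measure table; non-numeric columns are ignored.
#' @return Symmetric correlation matrix with measure labels.
#' @export
measure_correlations <- function(m) {
  num <- m[vapply(m, is.numeric, logical(1))]
  if (nrow(num) < 3) stop("need at least 3 animals", call. = FALSE)
  const <- vapply(num, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                    all(is.na(v)), logical(1))
  if (any(const)) {
    warning("constant measure(s), correlations undefined: ",
            paste(names(num)[const], collapse = ", "), call. = FALSE)
  }
  suppressWarnings(stats::cor(as.matrix(num), use = "pairwise.complete.obs"))
}
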