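#' Scan configuration for the ROH genome scan
#'
#' @param n_roh Minimum run length in SNPs defining the ROH covariate
#'   (default 50; must be >= 2).
#' @param p_threshold Significance threshold on the ROH-effect p-value
#'   (default 0.001).
#' @param min_carriers Minimum number of phenotyped animals carrying the
#'   ROH at a position for it to be testable (default 10; guards numerical
#'   stability only, set to 1 to disable).
#' @param indicator_mode `"window_start"` (position marks a fully
#'   homozygous window of `n_roh` SNPs starting there) or `"covering"`
#'   (position lies inside a maximal run of at least `n_roh` SNPs).
#' @return A list of class `gwas_config`.
#' @export
gwas_config <- function(n_roh = 50, p_threshold = 0.001, min_carriers = 10,
                        indicator_mode = c("window_start", "covering")) {
  indicator_mode <- match.arg(indicator_mode)
  stopifnot(n_roh >= 2, p_threshold > 0, p_threshold < 1, min_carriers >= 1)
  structure(list(n_roh = as.integer(n_roh), p_threshold = p_threshold,
                 min_carriers = as.integer(min_carriers),
                 indicator_mode = indicator_mode),
            class = "gwas_config")
}

#' Sliding-window genome scan of ROH effects
#'
#' For every SNP position, fits the repeated-records animal model with two
#' extra covariates: the genotype code at the SNP (additive correction,
#' coefficient `b3`) and a 0/1 run-of-homozygosity indicator at the
#' position (coefficient `b4`, the recessive/haplotype effect of being
#' homozygous across the window). Variance components are held fixed
#' across positions (estimate them once under the covariate-free null
#' model, or supply known values), so each position requires only two
#' triangular solves against the factorised null mixed-model equations.
#'
#' Positions are skipped - never fatal - when the window would leave the
#' chromosome, when fewer than `min_carriers` phenotyped animals carry the
#' ROH, when the indicator is constant, or when the SNP and ROH covariates
#' are collinear with the model; the skip reason is recorded.
#'
#' @inheritParams estimate_variance_components
#' @param g A [geno_matrix] covering the phenotyped cows.
#' @param cfg A [gwas_config].
#' @param vc Variance components (`vc_est` or list with `sigma2_a`,
#'   `sigma2_pe`, `sigma2_e`); if `NULL`, estimated by REML under the
#'   null model.
#' @return Object of class `roh_scan`: a tibble with one row per SNP
#'   (`snp_id`, `chr`, `pos_bp`, `b3`, `b4`, `se4`, `neglog10_p4`,
#'   `roh_frequency`, `tested`, `skip_reason`), with the configuration,
#'   the variance components and the number of phenotyped animals kept as
#'   attributes.
#' @export
roh_gwas_scan <- function(phen, ped, g, cfg = gwas_config(), vc = NULL,
                          fixed = ~ hys + parity + month + age_fc,
                          trait = NULL) {
  phen <- normalize_phen(phen, trait)
  if (is.null(vc)) {
    vc <- estimate_variance_components(phen, ped, fixed = fixed)
  }
  fx <- build_fixed_design(phen, fixed)
  rd <- build_random_design(phen, ped)
  base <- solve_mme_core(phen$value, fx$X, rd$Zu, rd$W, rd$Ainv, vc)
  M <- base_design_matrix(fx$X, rd, vc)
  ch <- base$chol
  theta0 <- base$theta
  sigma_e2 <- vc$sigma2_e
  y <- phen$value

  cows <- unique(phen$cow)
  not_geno <- setdiff(cows, rownames(g$codes))
  if (length(not_geno)) {
    stop("phenotyped cow(s) without genotypes: ",
         paste(utils::head(not_geno, 5), collapse = ", "), call. = FALSE)
  }
  arow <- match(phen$cow, rownames(g$codes))
  ind_all <- roh_indicator(g, cfg$n_roh, cfg$indicator_mode)
  codes <- g$codes
  map <- g$map
  n_snp <- ncol(codes)
  n_animal_rows <- match(cows, rownames(codes))

  b3 <- b4 <- se4 <- p4 <- freq <- rep(NA_real_, n_snp)
  tested <- logical(n_snp)
  reason <- rep(NA_character_, n_snp)

  for (i in seq_len(n_snp)) {
    ind_a <- ind_all[n_animal_rows, i]
    if (all(is.na(ind_a))) {
      reason[i] <- "window outside chromosome"
      next
    }
    carriers <- sum(ind_a == 1L, na.rm = TRUE)
    freq[i] <- carriers / length(cows)
    if (carriers == 0L || carriers == length(cows)) {
      reason[i] <- "constant covariate"
      next
    }
    if (carriers < cfg$min_carriers) {
      reason[i] <- "too few carriers"
      next
    }
    snp_rec <- codes[arow, i]
    snp_rec[is.na(snp_rec)] <- mean(snp_rec, na.rm = TRUE) # mean-impute
    roh_rec <- ind_all[arow, i]
    u <- cbind(snp = snp_rec, roh = as.numeric(roh_rec))
    est <- added_covariate_solve(M, ch, theta0, y, u, sigma_e2)
    if (is.null(est)) {
      reason[i] <- "collinear"
      next
    }
    tested[i] <- TRUE
    b3[i] <- est$b[1]
    b4[i] <- est$b[2]
    se4[i] <- est$se[2]
    p4[i] <- wald_neglog10p(est$b[2] / est$se[2])
  }

  res <- tibble::tibble(snp_id = map$snp_id, chr = map$chr,
                        pos_bp = map$pos_bp, b3 = b3, b4 = b4, se4 = se4,
                        neglog10_p4 = p4, roh_frequency = freq,
                        tested = tested, skip_reason = reason)
  class(res) <- c("roh_scan", class(res))
  attr(res, "config") <- cfg
  attr(res, "vc") <- vc
  attr(res, "n_animals") <- length(cows)
  res
}

# full (sparse) design matrix matching the block layout of solve_mme_core
base_design_matrix <- function(X, rd, vc) {
  blocks <- list(methods::as(X, "CsparseMatrix"))
  if (vc$sigma2_a > 0) blocks <- c(blocks, list(rd$Zu))
  if (vc$sigma2_pe > 0) blocks <- c(blocks, list(rd$W))
  do.call(cbind, blocks)
}

# Exact GLS estimate of covariates `u` added to an already-factorised
# mixed model, via the Schur complement of the bordered MME.
added_covariate_solve <- function(M, ch, theta0, y, u, sigma_e2,
                                  cond_tol = 1e-8) {
  B <- Matrix::crossprod(M, u)                    # dim x k
  Yb <- Matrix::solve(ch, B, system = "A")        # M0^{-1} B
  S <- as.matrix(Matrix::crossprod(u) - Matrix::crossprod(B, Yb))
  sv <- svd(S, nu = 0, nv = 0)$d
  if (min(sv) <= cond_tol * max(sv)) return(NULL)
  ru <- as.numeric(crossprod(u, y))
  rhs <- ru - as.numeric(Matrix::crossprod(B, theta0))
  Sinv <- solve(S)
  b <- as.numeric(Sinv %*% rhs)
  list(b = b, se = sqrt(pmax(diag(Sinv), 0) * sigma_e2))
}

#' Expected-false-positive FDR for a genome scan
#'
#' Bolormaa-style false discovery rate for `A` significant tests out of
#' `T` at threshold `p`:
#' `FDR = p (1 - A/T) / ((A/T) (1 - p))`, i.e. the expected proportion of
#' false positives among the significant tests. Can exceed 1; a capped
#' variant is reported alongside.
#'
#' @param A Number of significant tests (> 0).
#' @param T Number of tests performed (>= A).
#' @param p Significance threshold in (0, 1).
#' @return One-row tibble: `A`, `T`, `p`, `fdr` (proportion, uncapped),
#'   `fdr_pct`, `fdr_capped`.
#' @export
bolormaa_fdr <- function(A, T, p = 0.001) {
  if (A <= 0) stop("no significant tests (A = 0): FDR undefined", call. = FALSE)
  stopifnot(A <= T, p > 0, p < 1)
  rate <- A / T
  fdr <- p * (1 - rate) / (rate * (1 - p))
  tibble::tibble(A = A, T = T, p = p, fdr = fdr, fdr_pct = 100 * fdr,
                 fdr_capped = min(fdr, 1))
}

#' Cluster significant scan positions into QTL regions
#'
#' Significant positions (`neglog10_p4 > -log10(p_threshold)`) whose
#' `n_roh`-SNP windows overlap and whose effects share a sign are merged
#' into regions. Region bounds run from the first window start to the last
#' window end. The direction is labelled favourable/unfavourable from the
#' effect sign and the trait polarity (for a higher-is-better trait such
#' as milk yield a negative effect is unfavourable; for calving interval,
#' where lower is better, a positive effect is unfavourable).
#'
#' @param res A `roh_scan`.
#' @param cfg The scan's [gwas_config] (default: taken from `res`).
#' @param trait_polarity `"higher_better"` or `"lower_better"`.
#' @return Tibble with one row per region: `chr`, `start_bp`, `end_bp`,
#'   `n_significant`, `mean_frequency`, `mean_b`, `max_neglog10_p`,
#'   `peak_snp_id`, `peak_se`, `direction`.
#' @export
cluster_significant <- function(res, cfg = attr(res, "config"),
                                trait_polarity = c("higher_better",
                                                   "lower_better")) {
  trait_polarity <- match.arg(trait_polarity)
  if (is.null(cfg)) cfg <- gwas_config()
  thr <- -log10(cfg$p_threshold)
  sig <- res[res$tested & !is.na(res$neglog10_p4) & res$neglog10_p4 > thr, ]
  empty <- tibble::tibble(chr = character(), start_bp = integer(),
                          end_bp = integer(), n_significant = integer(),
                          mean_frequency = double(), mean_b = double(),
                          max_neglog10_p = double(), peak_snp_id = character(),
                          peak_se = double(), direction = character())
  if (!nrow(sig)) return(empty)
  # window extent of each significant position, in SNP index space
  all_idx <- seq_len(nrow(res))
  sig$idx <- match(sig$snp_id, res$snp_id)
  n <- cfg$n_roh
  win_end_idx <- function(i, chr) {
    j <- min(i + n - 1L, max(all_idx[res$chr == chr]))
    j
  }
  sig$win_end <- mapply(win_end_idx, sig$idx, sig$chr)
  sig$sign <- sign(sig$b4)
  out <- list()
  for (key in unique(paste(sig$chr, sig$sign))) {
    blk <- sig[paste(sig$chr, sig$sign) == key, ]
    blk <- blk[order(blk$idx), ]
    cur_start <- blk$idx[1]
    cur_end <- blk$win_end[1]
    members <- 1L
    flush <- function(start, end, rows) {
      m <- blk[rows, ]
      peak <- m[which.max(m$neglog10_p4), ]
      tibble::tibble(
        chr = m$chr[1],
        start_bp = res$pos_bp[start], end_bp = res$pos_bp[end],
        n_significant = nrow(m),
        mean_frequency = mean(m$roh_frequency),
        mean_b = mean(m$b4),
        max_neglog10_p = max(m$neglog10_p4),
        peak_snp_id = peak$snp_id, peak_se = peak$se4,
        direction = region_direction(m$sign[1], trait_polarity))
    }
    rows <- 1L
    for (r in seq_len(nrow(blk))[-1]) {
      if (blk$idx[r] <= cur_end) { # windows overlap
        cur_end <- max(cur_end, blk$win_end[r])
        rows <- c(rows, r)
      } else {
        out[[length(out) + 1L]] <- flush(cur_start, cur_end, rows)
        cur_start <- blk$idx[r]
        cur_end <- blk$win_end[r]
        rows <- r
      }
    }
    out[[length(out) + 1L]] <- flush(cur_start, cur_end, rows)
  }
  regions <- dplyr::bind_rows(out)
  dplyr::arrange(regions, chr_rank(.data$chr), .data$start_bp)
}

region_direction <- function(sgn, trait_polarity) {
  if (trait_polarity == "higher_better") {
    if (sgn < 0) "unfavourable" else "favourable"
  } else {
    if (sgn > 0) "unfavourable" else "favourable"
  }
}

#' Region summary table
#'
#' Formats clustered regions for reporting: chromosome, interval in Mb
#' (2 decimals), count of significant positions, mean ROH frequency in %,
#' mean effect with the standard error of the peak position, and the peak
#' `-log10` p-value.
#'
#' @param regions Output of [cluster_significant()].
#' @param res The originating `roh_scan` (unused beyond validation,
#'   retained for interface symmetry).
#' @return A tibble with presentation columns; zero rows when no region.
#' @export
summarize_regions <- function(regions, res = NULL) {
  tibble::tibble(
    chr = regions$chr,
    interval_mb = sprintf("%.2f-%.2f", regions$start_bp / 1e6,
                          regions$end_bp / 1e6),
    n_significant = regions$n_significant,
    mean_frequency_pct = round(100 * regions$mean_frequency, 1),
    mean_b = signif(regions$mean_b, 3),
    peak_se = signif(regions$peak_se, 3),
    peak_neglog10_p = round(regions$max_neglog10_p, 2),
    direction = regions$direction
  )
}

#' FDR of a completed scan
#'
#' Applies [bolormaa_fdr()] to a scan at its configured threshold. `T` is
#' the number of tested (non-skipped) positions by default; the total SNP
#' count variant is reported alongside.
#'
#' @param res A `roh_scan`.
#' @param cfg The scan's [gwas_config] (default: from `res`).
#' @return One-row tibble with `A`, `T_tested`, `T_total`, `fdr_tested`,
#'   `fdr_total` (each as proportions) and percent versions.
#' @export
scan_fdr <- function(res, cfg = attr(res, "config")) {
  if (is.null(cfg)) cfg <- gwas_config()
  thr <- -log10(cfg$p_threshold)
  A <- sum(res$tested & !is.na(res$neglog10_p4) & res$neglog10_p4 > thr)
  T_tested <- sum(res$tested)
  T_total <- nrow(res)
  if (A == 0) {
    return(tibble::tibble(A = 0L, T_tested = T_tested, T_total = T_total,
                          fdr_tested = NA_real_, fdr_total = NA_real_,
                          fdr_tested_pct = NA_real_, fdr_total_pct = NA_real_))
  }
  f1 <- bolormaa_fdr(A, T_tested, cfg$p_threshold)
  f2 <- bolormaa_fdr(A, T_total, cfg$p_threshold)
  tibble::tibble(A = as.integer(A), T_tested = T_tested, T_total = T_total,
                 fdr_tested = f1$fdr, fdr_total = f2$fdr,
                 fdr_tested_pct = f1$fdr_pct, fdr_total_pct = f2$fdr_pct)
}

#' @export
print.roh_scan <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<roh_scan> %d positions (%d tested), n_roh = %d, mode = %s\n",
              nrow(x), sum(x$tested), cfg$n_roh, cfg$indicator_mode))
  NextMethod()
}

#' Model-level summary of a scan
#'
#' @param x A `roh_scan`.
#' @param ... Unused.
#' @return One-row tibble: positions, tested, significant count at the
#'   configured threshold, and the tested-count FDR.
#' @exportS3Method generics::glance
glance.roh_scan <- function(x, ...) {
  f <- scan_fdr(x)
  tibble::tibble(n_positions = nrow(x), n_tested = f$T_tested,
                 n_significant = f$A, fdr = f$fdr_tested)
}
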