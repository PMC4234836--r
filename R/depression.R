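#' @importFrom Matrix crossprod t solve update
NULL

# ---- internal model assembly ------------------------------------------------

# Standardise a phenotype table: accept cow/cow_id, coerce factor columns.
normalize_phen <- function(phen, trait = NULL) {
  phen <- tibble::as_tibble(phen)
  if (!"cow" %in% names(phen) && "cow_id" %in% names(phen)) {
    phen <- dplyr::rename(phen, cow = "cow_id")
  }
  stopifnot("cow" %in% names(phen), "value" %in% names(phen))
  if ("trait" %in% names(phen)) {
    traits <- unique(phen$trait)
    if (!is.null(trait)) {
      phen <- phen[phen$trait == trait, ]
      if (!nrow(phen)) stop("no records for trait ", trait, call. = FALSE)
    } else if (length(traits) > 1) {
      stop("phenotype table has several traits (",
           paste(traits, collapse = ", "), "); pass `trait`", call. = FALSE)
    }
  }
  phen$cow <- as.character(phen$cow)
  phen
}

# Dense fixed-effect design with treatment contrasts and rank filtering.
# Returns X (dense), the kept column names, and names of dropped columns.
build_fixed_design <- function(phen, fixed = ~ hys + parity + month + age_fc,
                               covariates = NULL, rank_tol = 1e-9) {
  vars <- all.vars(fixed)
  miss <- setdiff(vars, names(phen))
  if (length(miss)) {
    stop("fixed-effect variable(s) absent from phenotype table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  mf <- phen[vars]
  for (v in intersect(c("hys", "parity", "month"), vars)) {
    mf[[v]] <- factor(mf[[v]])
  }
  # a factor with a single observed level carries no contrast
  single <- vapply(mf, function(v) is.factor(v) && nlevels(droplevels(v)) < 2,
                   logical(1))
  if (any(single)) {
    keep_terms <- setdiff(attr(stats::terms(fixed), "term.labels"),
                          names(mf)[single])
    fixed <- if (length(keep_terms)) stats::reformulate(keep_terms) else ~ 1
  }
  X <- stats::model.matrix(fixed, data = mf)
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    if (nrow(cv) != nrow(X)) {
      stop("covariates must have one value per record", call. = FALSE)
    }
    X <- cbind(X, cv)
  }
  qrx <- qr(X, tol = rank_tol)
  keep <- qrx$pivot[seq_len(qrx$rank)]
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  list(X = X[, sort(keep), drop = FALSE], dropped = dropped)
}

# Sparse incidence matrices and A-inverse for the animal model.
build_random_design <- function(phen, ped) {
  ai <- match(phen$cow, ped$animal)
  if (anyNA(ai)) {
    stop("phenotyped cow(s) not in pedigree: ",
         paste(utils::head(unique(phen$cow[is.na(ai)]), 5), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(phen)
  Zu <- Matrix::sparseMatrix(i = seq_len(n), j = ai,
                             x = 1, dims = c(n, nrow(ped)),
                             dimnames = list(NULL, ped$animal))
  cows <- sort(unique(phen$cow))
  W <- Matrix::sparseMatrix(i = seq_len(n), j = match(phen$cow, cows),
                            x = 1, dims = c(n, length(cows)),
                            dimnames = list(NULL, cows))
  Ainv <- a_inverse(ped)
  list(Zu = Zu, W = W, Ainv = Ainv, log_det_A = attr(Ainv, "log_det_A"),
       cows = cows)
}

# Profiled REML criterion machinery for the 2-random-effect animal model.
# Blocks: fixed (p), genetic (q_a, covariance A sigma_a^2), permanent
# environment (q_pe, I sigma_pe^2), residual I sigma_e^2.
make_reml_objective <- function(y, X, Zu, W, Ainv, log_det_A, use_pe = TRUE) {
  Xs <- methods::as(X, "CsparseMatrix")
  M <- if (use_pe) cbind(Xs, Zu, W) else cbind(Xs, Zu)
  C0 <- Matrix::crossprod(M)
  rhs <- as.numeric(Matrix::crossprod(M, y))
  p <- ncol(X)
  qa <- ncol(Zu)
  qpe <- if (use_pe) ncol(W) else 0L
  dim_all <- p + qa + qpe
  yy <- sum(y^2)
  n <- length(y)
  # fixed sparsity pattern: penalty blocks present from the first build
  pen <- function(ka, kp) {
    blocks <- list(Matrix::Diagonal(p, 0), ka * Ainv)
    if (use_pe) blocks <- c(blocks, list(Matrix::Diagonal(qpe, kp)))
    Matrix::bdiag(blocks)
  }
  ch <- NULL
  eval_at <- function(log_lambda) {
    la <- exp(log_lambda[1])
    lp <- if (use_pe) exp(log_lambda[2]) else NA_real_
    C <- methods::as(methods::as(
      C0 + pen(1 / la, if (use_pe) 1 / lp else 0), "symmetricMatrix"),
      "CsparseMatrix")
    if (is.null(ch)) {
      ch <<- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
    } else {
      ch <<- Matrix::update(ch, C)
    }
    theta <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
    Q <- max(yy - sum(theta * rhs), 1e-300)
    log_det_C <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    sigma_e2 <- Q / (n - p)
    m2l <- (n - p) * (log(2 * pi) + 1 + log(sigma_e2)) +
      qa * log(la) + (if (use_pe) qpe * log(lp) else 0) +
      log_det_A + log_det_C
    list(m2l = m2l, theta = theta, sigma_e2 = sigma_e2, chol = ch, C = C)
  }
  list(eval_at = eval_at, p = p, qa = qa, qpe = qpe, n = n, dim = dim_all,
       rhs = rhs, M = M, yy = yy)
}

#' Estimate variance components of the repeated-records animal model
#'
#' Restricted maximum likelihood for the model
#' `y = X b + Z u + W pe + e` with `u ~ N(0, A sigma_a^2)` (numerator
#' relationship matrix from the pedigree), `pe ~ N(0, I sigma_pe^2)` per
#' cow, and `e ~ N(0, I sigma_e^2)`. The REML log-likelihood is evaluated
#' exactly through a sparse Cholesky factorisation of the mixed-model
#' equations; the residual variance is profiled out analytically and the
#' two variance ratios are maximised numerically (Nelder-Mead on the log
#' scale, relative tolerance `tol`).
#'
#' Without repeated records the permanent-environment variance is not
#' identifiable and is fixed at zero with a warning.
#'
#' @param phen Phenotype table: columns `cow` (or `cow_id`), `value`, plus
#'   the fixed-effect variables (`hys`, `parity`, `month`, `age_fc` by
#'   default). A `trait` column is allowed; pass `trait` to pick one.
#' @param ped A [pedigree] covering every phenotyped cow.
#' @param fixed One-sided fixed-effects formula (default
#'   `~ hys + parity + month + age_fc`).
#' @param covariates Optional named list/data frame of extra per-record
#'   regressors to include among the fixed effects (e.g. the inbreeding
#'   measure the components will be reused with).
#' @param trait Trait to select when `phen` holds several.
#' @param tol Relative convergence tolerance on the REML criterion
#'   (default 1e-12).
#' @param max_iter Maximum criterion evaluations per optimiser pass
#'   (default 1000).
#' @return Object of class `vc_est`: list with `sigma2_a`, `sigma2_pe`,
#'   `sigma2_e`, `loglik` (REML), `n_records`, `n_cows`, `iterations`,
#'   `converged`.
#' @export
estimate_variance_components <- function(phen, ped,
                                         fixed = ~ hys + parity + month + age_fc,
                                         covariates = NULL, trait = NULL,
                                         tol = 1e-12, max_iter = 1000) {
  phen <- normalize_phen(phen, trait)
  fx <- build_fixed_design(phen, fixed, covariates)
  rd <- build_random_design(phen, ped)
  use_pe <- any(duplicated(phen$cow))
  if (!use_pe) {
    warning("no cow has repeated records; sigma2_pe fixed at 0", call. = FALSE)
  }
  obj <- make_reml_objective(phen$value, fx$X, rd$Zu, rd$W, rd$Ainv,
                             rd$log_det_A, use_pe = use_pe)
  vy <- stats::var(phen$value)
  f <- function(par) obj$eval_at(par)$m2l
  start <- if (use_pe) log(c(0.3, 0.2)) else log(0.3)
  opt <- if (use_pe) {
    o1 <- stats::optim(start, f, method = "Nelder-Mead",
                       control = list(reltol = tol, maxit = max_iter))
    # restart from the optimum: Nelder-Mead polishing pass
    o2 <- stats::optim(o1$par, f, method = "Nelder-Mead",
                       control = list(reltol = tol, maxit = max_iter))
    o2$counts[1] <- o2$counts[1] + o1$counts[1]
    o2
  } else {
    stats::optim(start, f, method = "Brent", lower = log(1e-8),
                 upper = log(1e8), control = list(maxit = max_iter))
  }
  fin <- obj$eval_at(opt$par)
  sigma_e2 <- fin$sigma_e2
  sigma_a2 <- exp(opt$par[1]) * sigma_e2
  sigma_pe2 <- if (use_pe) exp(opt$par[2]) * sigma_e2 else 0
  structure(list(sigma2_a = sigma_a2, sigma2_pe = sigma_pe2,
                 sigma2_e = sigma_e2,
                 loglik = -fin$m2l / 2,
                 n_records = nrow(phen), n_cows = length(rd$cows),
                 iterations = as.integer(opt$counts[1]),
                 converged = opt$convergence == 0,
                 heritability = sigma_a2 / (sigma_a2 + sigma_pe2 + sigma_e2),
                 repeatability = (sigma_a2 + sigma_pe2) /
                   (sigma_a2 + sigma_pe2 + sigma_e2)),
            class = "vc_est")
}

#' @export
print.vc_est <- function(x, ...) {
  cat(sprintf(paste0(
    "<vc_est> REML variance components (%d records, %d cows)\n",
    "  sigma2_a = %.6g  sigma2_pe = %.6g  sigma2_e = %.6g\n",
    "  h2 = %.3f  repeatability = %.3f  logLik = %.3f  (%d evals%s)\n"),
    x$n_records, x$n_cows, x$sigma2_a, x$sigma2_pe, x$sigma2_e,
    x$heritability, x$repeatability, x$loglik, x$iterations,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Solve the mixed-model equations at given variance components
#'
#' Assembles and solves Henderson's mixed-model equations for the
#' repeated-records animal model, with the pedigree `A`-inverse for the
#' genetic effect and an identity for the permanent-environment effect.
#' Factor levels use treatment contrasts (first level as reference);
#' rank-deficient fixed-effect columns are dropped and reported as
#' inestimable. With both random variances zero and single records the
#' solutions collapse to ordinary least squares.
#'
#' Standard errors come from the corresponding diagonal block of the
#' inverse coefficient matrix times `sigma2_e`; p-values are two-sided
#' Wald z-tests.
#'
#' @inheritParams estimate_variance_components
#' @param covariates Named list/data frame of per-record regressors whose
#'   coefficients are of primary interest (inbreeding measures, SNP codes).
#' @param vc A `vc_est` or list with `sigma2_a`, `sigma2_pe`, `sigma2_e`.
#' @return Object of class `ibd_fit`; see [tidy.ibd_fit()].
#' @export
solve_mme <- function(phen, ped, covariates = NULL, vc,
                      fixed = ~ hys + parity + month + age_fc, trait = NULL) {
  phen <- normalize_phen(phen, trait)
  fx <- build_fixed_design(phen, fixed, covariates)
  rd <- build_random_design(phen, ped)
  fit <- solve_mme_core(phen$value, fx$X, rd$Zu, rd$W, rd$Ainv, vc)
  coefs <- tibble::tibble(
    term = colnames(fx$X),
    estimate = fit$beta,
    std_error = fit$se_beta,
    statistic = fit$beta / fit$se_beta,
    neglog10_p = wald_neglog10p(fit$beta / fit$se_beta)
  )
  if (length(fx$dropped)) {
    coefs <- dplyr::bind_rows(coefs, tibble::tibble(
      term = fx$dropped, estimate = NA_real_, std_error = NA_real_,
      statistic = NA_real_, neglog10_p = NA_real_))
  }
  structure(list(coefficients = coefs, inestimable = fx$dropped,
                 vc = vc, n_records = nrow(phen),
                 n_cows = length(rd$cows),
                 u_hat = fit$u_hat, pe_hat = fit$pe_hat,
                 measure_terms = names(covariates)),
            class = "ibd_fit")
}

# two-sided normal tail on the -log10 scale, accurate far in the tail
wald_neglog10p <- function(z) {
  -(log(2) + stats::pnorm(-abs(z), log.p = TRUE)) / log(10)
}

# Core MME solve. Zero variance components drop the corresponding random
# block (sigma_a2 = sigma_pe2 = 0 reduces to OLS/GLS on the fixed part).
solve_mme_core <- function(y, X, Zu, W, Ainv, vc) {
  sigma_a2 <- vc$sigma2_a
  sigma_pe2 <- vc$sigma2_pe
  sigma_e2 <- vc$sigma2_e
  stopifnot(sigma_e2 > 0)
  p <- ncol(X)
  use_u <- sigma_a2 > 0
  use_pe <- sigma_pe2 > 0
  Xs <- methods::as(X, "CsparseMatrix")
  blocks <- list(Xs)
  pens <- list(Matrix::Diagonal(p, 0))
  if (use_u) {
    blocks <- c(blocks, list(Zu))
    pens <- c(pens, list((sigma_e2 / sigma_a2) * Ainv))
  }
  if (use_pe) {
    blocks <- c(blocks, list(W))
    pens <- c(pens, list(Matrix::Diagonal(ncol(W), sigma_e2 / sigma_pe2)))
  }
  M <- do.call(cbind, blocks)
  C <- methods::as(methods::as(Matrix::crossprod(M) + Matrix::bdiag(pens),
                               "symmetricMatrix"), "CsparseMatrix")
  rhs <- as.numeric(Matrix::crossprod(M, y))
  ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
  theta <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  # fixed-effect block of C^{-1} for standard errors
  Efix <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                               dims = c(nrow(C), p))
  Cinv_fix <- Matrix::solve(ch, Efix, system = "A")
  se <- sqrt(pmax(Matrix::diag(Matrix::t(Efix) %*% Cinv_fix), 0) * sigma_e2)
  beta <- theta[seq_len(p)]
  u_hat <- if (use_u) {
    stats::setNames(theta[p + seq_len(ncol(Zu))], colnames(Zu))
  } else NULL
  pe_hat <- if (use_pe) {
    off <- p + if (use_u) ncol(Zu) else 0L
    stats::setNames(theta[off + seq_len(ncol(W))], colnames(W))
  } else NULL
  list(beta = stats::setNames(beta, colnames(X)),
       se_beta = stats::setNames(as.numeric(se), colnames(X)),
       u_hat = u_hat, pe_hat = pe_hat, chol = ch, theta = theta)
}

# ---- inbreeding-depression front end ---------------------------------------

measure_column <- function(measure, n_roh) {
  switch(measure,
         pedigree = "f_ped",
         grm_f = "grm_f",
         homozygosity = "homozygosity",
         roh_f = paste0("roh_f_", n_roh),
         stop("unknown measure: ", measure, call. = FALSE))
}

#' Regress phenotypes on an inbreeding measure (inbreeding depression)
#'
#' End-to-end fit of the repeated-records animal model with an inbreeding
#' measure as a fixed covariate: computes the requested measure(s) per cow,
#' estimates variance components by REML (unless supplied), and solves the
#' mixed-model equations. The coefficient on the measure estimates
#' inbreeding depression; it is reported both per unit of the measure
#' (proportion scale) and per 1% (`estimate / 100`).
#'
#' A second measure can be fitted jointly (e.g. pedigree inbreeding
#' together with a genomic measure, or ROH-based inbreeding together with
#' overall homozygosity); `quadratic = TRUE` adds the squared measure.
#'
#' @inheritParams estimate_variance_components
#' @param g A [geno_matrix] (required for genomic measures).
#' @param measure One of `"pedigree"`, `"grm_f"`, `"homozygosity"`,
#'   `"roh_f"`.
#' @param joint_with Optional second measure fitted simultaneously.
#' @param quadratic Add the squared primary measure as a covariate.
#' @param vc Optional variance components to reuse; estimated by REML when
#'   `NULL`.
#' @param n_roh Minimum ROH length in SNPs for `measure = "roh_f"`
#'   (default 50).
#' @param measures Optional precomputed table from
#'   [inbreeding_measures()] (or with the needed columns) to avoid
#'   recomputation.
#' @return An `ibd_fit`; the measure rows of [tidy.ibd_fit()] carry the
#'   depression estimates.
#' @export
fit_inbreeding_depression <- function(phen, ped, g = NULL,
                                      measure = c("pedigree", "grm_f",
                                                  "homozygosity", "roh_f"),
                                      joint_with = NULL, quadratic = FALSE,
                                      vc = NULL, n_roh = 50,
                                      fixed = ~ hys + parity + month + age_fc,
                                      trait = NULL, measures = NULL) {
  measure <- match.arg(measure)
  wanted <- c(measure, joint_with)
  if (any(wanted != "pedigree") && is.null(g) && is.null(measures)) {
    stop("genomic measure '", setdiff(wanted, "pedigree")[1],
         "' requested but no genotypes given", call. = FALSE)
  }
  phen <- normalize_phen(phen, trait)
  if (is.null(measures)) {
    measures <- if (all(wanted == "pedigree")) {
      dplyr::rename(inbreeding_ml(ped), f_ped = "F")
    } else {
      inbreeding_measures(ped, g, n_grid = unique(c(1L, n_roh)))
    }
  }
  cols <- vapply(wanted, measure_column, character(1), n_roh = n_roh)
  miss <- setdiff(cols, names(measures))
  if (length(miss)) {
    stop("measure table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(phen$cow, measures$animal)
  if (anyNA(idx)) {
    stop("no inbreeding measure for cow(s): ",
         paste(utils::head(unique(phen$cow[is.na(idx)]), 5), collapse = ", "),
         call. = FALSE)
  }
  covs <- stats::setNames(
    lapply(cols, function(cl) measures[[cl]][idx]), cols)
  if (quadratic) covs[[paste0(cols[1], "_sq")]] <- covs[[cols[1]]]^2
  if (is.null(vc)) {
    vc <- estimate_variance_components(phen, ped, fixed = fixed,
                                       covariates = covs)
  }
  fit <- solve_mme(phen, ped, covariates = covs, vc = vc, fixed = fixed)
  fit$measure_terms <- names(covs)
  fit$measure <- measure
  fit
}

#' Depression estimates per 1% inbreeding
#'
#' Convenience view of the inbreeding-measure coefficients of an
#' `ibd_fit`, rescaled to the effect of a 1 percentage-point increase in
#' the measure (`estimate / 100`).
#'
#' @param fit An `ibd_fit`.
#' @return Tibble with `term`, `b_per_unit`, `b_per_pct`, `se_per_pct`,
#'   `neglog10_p`.
#' @export
depression_per_pct <- function(fit) {
  stopifnot(inherits(fit, "ibd_fit"))
  co <- fit$coefficients[fit$coefficients$term %in% fit$measure_terms, ]
  tibble::tibble(term = co$term,
                 b_per_unit = co$estimate,
                 se_per_unit = co$std_error,
                 b_per_pct = co$estimate / 100,
                 se_per_pct = co$std_error / 100,
                 neglog10_p = co$neglog10_p)
}

#' @export
print.ibd_fit <- function(x, ...) {
  cat(sprintf("<ibd_fit> animal-model fit: %d records, %d cows\n",
              x$n_records, x$n_cows))
  cat(sprintf("  vc: sigma2_a = %.4g, sigma2_pe = %.4g, sigma2_e = %.4g\n",
              x$vc$sigma2_a, x$vc$sigma2_pe, x$vc$sigma2_e))
  if (length(x$measure_terms)) {
    print(depression_per_pct(x))
  }
  if (length(x$inestimable)) {
    cat("  inestimable terms:", paste(x$inestimable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy an animal-model fit
#'
#' @param x An `ibd_fit` from [solve_mme()] or
#'   [fit_inbreeding_depression()].
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect term: `term`,
#'   `estimate`, `std_error`, `statistic`, `neglog10_p`.
#' @exportS3Method generics::tidy
tidy.ibd_fit <- function(x, ...) x$coefficients

#' Model-level summary of an animal-model fit
#'
#' @param x An `ibd_fit`.
#' @param ... Unused.
#' @return One-row tibble with the variance components, counts and (when
#'   estimated here) the REML log-likelihood.
#' @exportS3Method generics::glance
glance.ibd_fit <- function(x, ...) {
  tibble::tibble(sigma2_a = x$vc$sigma2_a, sigma2_pe = x$vc$sigma2_pe,
                 sigma2_e = x$vc$sigma2_e,
                 loglik = if (!is.null(x$vc$loglik)) x$vc$loglik else NA_real_,
                 n_records = x$n_records, n_cows = x$n_cows)
}

#' Write an inbreeding-depression fit as TSV
#'
#' One row per fitted inbreeding measure with the per-1% coefficient,
#' mirroring the `b (s.e.)` / `-log10(P)` presentation customary for
#' depression tables.
#'
#' @param fit An `ibd_fit`.
#' @param path Output path.
#' @export
write_fit <- function(fit, path) {
  readr::write_tsv(depression_per_pct(fit), path)
  invisible(path)
}
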