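test_that("solver collapses to OLS with zero random variances and single records", {
  sp <- simple_phen(80, k = 1, seed = 2)
  vc0 <- list(sigma2_a = 0, sigma2_pe = 0, sigma2_e = 2)
  fit <- solve_mme(sp$phen, sp$ped, vc = vc0)
  # parity has a single level with k = 1 and drops out of the model
  X <- model.matrix(~ factor(hys) + factor(month) + age_fc, sp$phen)
  ols <- lm.fit(X, sp$phen$value)
  td <- tidy(fit)
  est <- td$estimate[!is.na(td$estimate)]
  expect_lt(max(abs(sort(est) - sort(ols$coefficients))), 1e-8)
})

test_that("solutions match a dense GLS oracle on a toy related dataset", {
  ped <- pedigree(data.frame(animal = c("s", "d", "c1", "c2"),
                             sire = c(NA, NA, "s", "s"),
                             dam = c(NA, NA, "d", "d"),
                             sex = c("M", "F", "F", "F")))
  dat <- tibble::tibble(cow = c("c1", "c1", "c2", "c2", "c2"),
                        hys = c(1, 2, 1, 2, 2), parity = c(1, 2, 1, 2, 3),
                        month = c(3, 4, 3, 5, 6),
                        age_fc = c(24, 24, 27, 27, 27),
                        value = c(10.2, 11.5, 9.1, 8.8, 9.9))
  vc <- list(sigma2_a = 2, sigma2_pe = 1, sigma2_e = 3)
  fit <- solve_mme(dat, ped, vc = vc, fixed = ~ age_fc)
  A <- relationship_matrix_tabular(ped)[c("c1", "c2"), c("c1", "c2")]
  Z <- model.matrix(~ 0 + cow, dat)
  V <- Z %*% (2 * A + diag(2)) %*% t(Z) + diag(5) * 3
  X <- model.matrix(~ age_fc, dat)
  Vb <- solve(t(X) %*% solve(V) %*% X)
  b <- drop(Vb %*% t(X) %*% solve(V) %*% dat$value)
  td <- tidy(fit)
  expect_lt(max(abs(td$estimate - b)), 1e-8)
  expect_lt(max(abs(td$std_error - sqrt(diag(Vb)))), 1e-8)
})

test_that("fit is invariant to record order", {
  sp <- simple_phen(50, k = 3, seed = 5)
  vc <- list(sigma2_a = 0.5, sigma2_pe = 0.3, sigma2_e = 1)
  f1 <- solve_mme(sp$phen, sp$ped, vc = vc)
  set.seed(1)
  f2 <- solve_mme(sp$phen[sample(nrow(sp$phen)), ], sp$ped, vc = vc)
  expect_equal(tidy(f2)$estimate, tidy(f1)$estimate, tolerance = 1e-10)
  expect_equal(tidy(f2)$std_error, tidy(f1)$std_error, tolerance = 1e-10)
})

test_that("REML matches closed-form ANOVA on a balanced one-way layout", {
  # unrelated cows, k records each, no fixed effects beyond the mean:
  # repeatability model with sigma_b^2 (between) and sigma_e^2 (within)
  set.seed(10)
  nc <- 120; k <- 4
  cows <- sprintf("c%03d", seq_len(nc))
  ped <- pedigree(data.frame(animal = cows, sire = NA, dam = NA, sex = "F"))
  b <- rnorm(nc, 0, sqrt(3))
  y <- rep(b, each = k) + rnorm(nc * k, 0, sqrt(2))
  phen <- tibble::tibble(cow = rep(cows, each = k), value = y)
  vc <- estimate_variance_components(phen, ped, fixed = ~ 1)
  # ANOVA estimators: MSW = sigma_e^2, (MSB - MSW)/k = sigma_b^2
  grp <- rep(seq_len(nc), each = k)
  msw <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2))) / (nc * (k - 1))
  msb <- k * sum((tapply(y, grp, mean) - mean(y))^2) / (nc - 1)
  expect_equal(vc$sigma2_e, msw, tolerance = 1e-6)
  # between-cow variance splits between genetic and permanent components
  # (unidentifiable split with A = I); their sum matches ANOVA
  expect_equal(vc$sigma2_a + vc$sigma2_pe, (msb - msw) / k, tolerance = 1e-5)
})

test_that("REML matches lme4 on unrelated cows (criterion and residual)", {
  skip_if_not_installed("lme4")
  set.seed(7)
  nc <- 150; k <- 3
  cows <- sprintf("c%03d", seq_len(nc))
  ped <- pedigree(data.frame(animal = cows, sire = NA, dam = NA, sex = "F"))
  u <- rnorm(nc, 0, 2)
  pe <- rnorm(nc, 0, 1.5)
  dat <- tibble::tibble(cow = rep(cows, each = k),
                        hys = sample(1:6, nc * k, TRUE),
                        parity = rep(1:k, nc),
                        month = sample(1:12, nc * k, TRUE),
                        age_fc = round(rnorm(nc * k, 26, 2), 2))
  dat$value <- 10 + 0.3 * dat$age_fc + (1:6 / 3)[dat$hys] +
    u[rep(1:nc, each = k)] + pe[rep(1:nc, each = k)] + rnorm(nc * k, 0, 2.5)
  vc <- estimate_variance_components(dat, ped)
  m <- suppressWarnings(lme4::lmer(
    value ~ factor(hys) + factor(parity) + factor(month) + age_fc +
      (1 | cow) + (1 | cow2),
    data = transform(dat, cow2 = cow), REML = TRUE,
    control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.nRE = "ignore")))
  v <- as.data.frame(lme4::VarCorr(m))
  expect_equal(-2 * vc$loglik, lme4::REMLcrit(m), tolerance = 1e-4)
  expect_equal(vc$sigma2_e, v$vcov[v$grp == "Residual"], tolerance = 1e-3)
  expect_equal(vc$sigma2_a + vc$sigma2_pe,
               sum(v$vcov[v$grp != "Residual"]), tolerance = 1e-2)
})

test_that("REML recovers a zero genetic variance at the boundary", {
  set.seed(15)
  nc <- 200; k <- 3
  # sire families so sigma_a would be identifiable if present
  sires <- sprintf("s%02d", 1:20)
  cows <- sprintf("c%03d", seq_len(nc))
  ped <- pedigree(dplyr::bind_rows(
    tibble::tibble(animal = sires, sire = NA, dam = NA, sex = "M"),
    tibble::tibble(animal = cows, sire = rep(sires, each = 10), dam = NA,
                   sex = "F")))
  pe <- rnorm(nc, 0, 1)
  y <- 5 + rep(pe, each = k) + rnorm(nc * k, 0, 2) # no genetic signal
  phen <- tibble::tibble(cow = rep(cows, each = k), value = y)
  vc <- estimate_variance_components(phen, ped, fixed = ~ 1)
  expect_lt(vc$sigma2_a, 0.05 * vc$sigma2_e)
})

test_that("no repeated records fixes sigma2_pe at zero with a warning", {
  sp <- simple_phen(60, k = 1, seed = 3)
  expect_warning(vc <- estimate_variance_components(sp$phen, sp$ped),
                 "sigma2_pe")
  expect_equal(vc$sigma2_pe, 0)
})

test_that("depression coefficient is recovered within 2 reported s.e.", {
  cfg <- sim_config(n_founders = 200, n_generations = 6,
                    n_sires_per_generation = 5,
                    n_offspring_per_generation = c(200, 200, 400, 400, 400, 400),
                    n_chromosomes = 2, snps_per_chromosome = 500,
                    depression_per_unit_F = -2500,
                    n_cows = 600, records_per_cow = 3, seed = 314)
  herd <- simulate_herd(cfg)
  fit <- fit_inbreeding_depression(herd$phenotypes, herd$pedigree,
                                   measure = "pedigree", vc = cfg$vc)
  dep <- depression_per_pct(fit)
  expect_lt(abs(dep$b_per_pct + 25), 2 * dep$se_per_pct)
  # per-1% coefficient is exactly the per-unit coefficient / 100
  expect_equal(dep$b_per_pct, dep$b_per_unit / 100)
  expect_equal(dep$se_per_pct, dep$se_per_unit / 100)
})

test_that("a null depression term is not significant", {
  cfg <- sim_config(n_founders = 150, n_generations = 5,
                    n_sires_per_generation = 6,
                    n_offspring_per_generation = 300,
                    n_chromosomes = 1, snps_per_chromosome = 300,
                    depression_per_unit_F = 0,
                    n_cows = 400, records_per_cow = 3, seed = 99)
  hits <- 0
  for (r in 1:5) {
    cfg$seed <- 99 + r
    herd <- simulate_herd(cfg)
    fit <- fit_inbreeding_depression(herd$phenotypes, herd$pedigree,
                                     measure = "pedigree", vc = cfg$vc)
    dep <- depression_per_pct(fit)
    hits <- hits + (abs(dep$b_per_unit) < 2 * dep$se_per_unit)
  }
  expect_gte(hits, 4) # ~95% coverage, allow one excursion in five
})

test_that("joint fit with a duplicated measure flags the copy inestimable", {
  cfg <- sim_config(n_founders = 100, n_generations = 4,
                    n_sires_per_generation = 5,
                    n_offspring_per_generation = 150,
                    n_chromosomes = 1, snps_per_chromosome = 200,
                    n_cows = 150, records_per_cow = 2, seed = 6)
  herd <- simulate_herd(cfg)
  meas <- dplyr::rename(inbreeding_ml(herd$pedigree), f_ped = "F")
  meas$grm_f <- meas$f_ped # second copy, perfectly collinear
  fit <- fit_inbreeding_depression(herd$phenotypes, herd$pedigree,
                                   measure = "pedigree", joint_with = "grm_f",
                                   vc = cfg$vc, measures = meas)
  expect_true("grm_f" %in% fit$inestimable || "f_ped" %in% fit$inestimable)
})

test_that("genomic measure without genotypes is fatal", {
  sp <- simple_phen(10, k = 1, seed = 1)
  expect_error(fit_inbreeding_depression(sp$phen, sp$ped, measure = "grm_f"),
               "no genotypes")
})

test_that("quadratic flag adds a squared-measure covariate", {
  cfg <- sim_config(n_founders = 100, n_generations = 4,
                    n_sires_per_generation = 4,
                    n_offspring_per_generation = 150,
                    n_chromosomes = 1, snps_per_chromosome = 200,
                    n_cows = 150, records_per_cow = 2, seed = 8)
  herd <- simulate_herd(cfg)
  fit <- fit_inbreeding_depression(herd$phenotypes, herd$pedigree,
                                   measure = "pedigree", quadratic = TRUE,
                                   vc = cfg$vc)
  expect_true("f_ped_sq" %in% fit$measure_terms)
  expect_true("f_ped_sq" %in% tidy(fit)$term)
})

test_that("tidy and glance expose coefficients and components", {
  sp <- simple_phen(40, k = 2, seed = 9)
  vc <- list(sigma2_a = 0.4, sigma2_pe = 0.2, sigma2_e = 1)
  fit <- solve_mme(sp$phen, sp$ped, vc = vc)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "neglog10_p") %in%
                    names(td)))
  expect_true(all(td$std_error[!is.na(td$std_error)] > 0))
  expect_true(all(td$neglog10_p[!is.na(td$neglog10_p)] >= 0))
  gl <- glance(fit)
  expect_equal(gl$n_cows, 40)
  expect_equal(gl$sigma2_e, 1)
})
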