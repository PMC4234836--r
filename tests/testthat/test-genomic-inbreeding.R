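test_that("geno_matrix validates codes and sorts the map", {
  codes <- rbind(a1 = c(0L, 1L, 2L), a2 = c(2L, NA, 0L))
  g <- toy_geno(codes, chr = c("2", "1", "1"), pos = c(500, 900, 100))
  expect_equal(g$map$chr, c("1", "1", "2"))
  expect_equal(g$map$pos_bp, c(100L, 900L, 500L))
  expect_equal(unname(g$codes["a1", ]), c(2L, 1L, 0L))
  expect_error(toy_geno(rbind(a1 = c(0L, 3L))), "codes")
})

test_that("PED/MAP reading codes by A1 allele count, order-independent", {
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1 snp1 0 1000", "1 snp2 0 2000", "1 snp3 0 3000"), map)
  pedf <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("f a1 0 0 2 -9 A A A G 0 0",
               "f a2 0 0 2 -9 A A G A G G"), pedf)
  g <- read_genotypes(pedf, map)
  expect_equal(unname(g$codes["a1", ]), c(2L, 1L, NA))
  # heterozygote codes 1 whatever the allele order; A1 of snp3 is G
  expect_equal(unname(g$codes["a2", ]), c(2L, 1L, 2L))
  bad <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("f a1 0 0 2 -9 A A A G C C",
               "f a2 0 0 2 -9 A A G A G T"), bad)
  expect_error(read_genotypes(bad, map), "more than two alleles")
  short <- withr::local_tempfile(fileext = ".ped")
  writeLines("f a1 0 0 2 -9 A A", short)
  expect_error(read_genotypes(short, map), "mismatch")
})

test_that("matrix TSV round-trips through write/read", {
  set.seed(5)
  codes <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 6, 10)
  rownames(codes) <- sprintf("cow%d", 1:6)
  g <- toy_geno(codes, chr = rep(c("1", "2"), each = 5))
  tf <- withr::local_tempfile(fileext = ".tsv")
  tm <- withr::local_tempfile(fileext = ".tsv")
  write_geno_tsv(g, tf, tm)
  g2 <- read_geno_tsv(tf, tm)
  expect_equal(g2$codes, g$codes)
  expect_equal(g2$map, g$map)
})

test_that("allele frequencies match brute-force allele counting", {
  g <- toy_geno(rbind(a1 = c(1L, 0L, 2L), a2 = c(1L, 1L, NA),
                      a3 = c(1L, 2L, 2L)))
  p <- allele_frequencies(g)
  expect_equal(p$p, c(0.5, 0.5, 1))
  expect_true(p$monomorphic[3])
  set.seed(8)
  codes <- matrix(sample(c(0:2, NA), 500, TRUE, prob = c(.3, .3, .3, .1)),
                  20, 25, dimnames = list(sprintf("x%d", 1:20), NULL))
  g2 <- toy_geno(codes)
  p2 <- allele_frequencies(g2)
  oracle <- apply(codes, 2, function(col) {
    alleles <- c(sum(col == 2, na.rm = TRUE) * 2 + sum(col == 1, na.rm = TRUE))
    alleles / (2 * sum(!is.na(col)))
  })
  expect_equal(p2$p, unname(oracle))
  # reference subset
  p3 <- allele_frequencies(g2, reference_ids = rownames(codes)[1:5])
  oracle3 <- colMeans(codes[1:5, ], na.rm = TRUE) / 2
  expect_equal(p3$p, unname(oracle3))
})

test_that("GRM self-relationship hits closed-form values and flip invariance", {
  # all heterozygous at p = 0.5 -> -1; all homozygous-2 at p = 0.5 -> +1
  g_het <- toy_geno(matrix(1L, 2, 10, dimnames = list(c("a", "b"), NULL)))
  p5 <- allele_frequencies(g_het)
  p5$p <- rep(0.5, 10)
  p5$monomorphic <- FALSE
  expect_equal(grm_self_relationship(g_het, p5)$grm_f, c(-1, -1))
  g_hom <- toy_geno(matrix(2L, 2, 10, dimnames = list(c("a", "b"), NULL)))
  expect_equal(grm_self_relationship(g_hom, p5)$grm_f, c(1, 1))
  # allele-label flip invariance: x -> 2 - x, p -> 1 - p
  set.seed(3)
  codes <- matrix(sample(0:2, 200, TRUE), 10, 20,
                  dimnames = list(sprintf("a%d", 1:10), NULL))
  g <- toy_geno(codes)
  p <- allele_frequencies(g)
  gf <- grm_self_relationship(g, p)
  flipped <- toy_geno(2L - codes)
  pf <- allele_frequencies(flipped)
  gff <- grm_self_relationship(flipped, pf)
  expect_equal(gff$grm_f, gf$grm_f, tolerance = 1e-12)
  # vanraden_diag variant also flip-invariant
  expect_equal(grm_self_relationship(flipped, pf, variant = "vanraden_diag")$grm_f,
               grm_self_relationship(g, p, variant = "vanraden_diag")$grm_f,
               tolerance = 1e-12)
})

test_that("Hardy-Weinberg founders have mean GRM_F near zero", {
  set.seed(21)
  n <- 400; m <- 1500
  p_true <- runif(m, 0.1, 0.5)
  codes <- sapply(p_true, function(p) rbinom(n, 2, p))
  rownames(codes) <- sprintf("f%03d", seq_len(n))
  g <- toy_geno(codes)
  gf <- grm_self_relationship(g, allele_frequencies(g))
  mc_se <- sd(gf$grm_f) / sqrt(n)
  expect_lt(abs(mean(gf$grm_f)), 3 * mc_se + 1e-3)
})

test_that("homozygosity proportion counts non-missing homozygotes", {
  g <- toy_geno(rbind(all_het = rep(1L, 10), all_hom = rep(c(0L, 2L), 5),
                      mix = c(rep(0L, 6), rep(1L, 4))))
  h <- homozygosity_proportion(g)
  expect_equal(h$homozygosity, c(0, 1, 0.6))
  gm <- toy_geno(rbind(a = c(0L, NA, 1L, 2L)))
  expect_equal(homozygosity_proportion(gm)$homozygosity, 2 / 3)
  g_allna <- toy_geno(rbind(a = rep(NA_integer_, 3), b = c(0L, 1L, 2L)))
  expect_error(homozygosity_proportion(g_allna), "missing")
})

test_that("ROH detection matches both brute-force oracles", {
  # 80 consecutive homozygous SNPs -> one run
  g <- toy_geno(matrix(2L, 1, 80, dimnames = list("a", NULL)))
  r <- detect_roh(g)
  expect_equal(nrow(r), 1)
  expect_equal(r$n_snps, 80L)
  # alternating -> only length-1 runs
  g2 <- toy_geno(matrix(rep(c(0L, 1L), 20), 1, 40, dimnames = list("a", NULL)))
  expect_true(all(detect_roh(g2)$n_snps == 1L))
  # quadratic all-pairs oracle on short random strings
  set.seed(12)
  for (i in 1:5) {
    codes <- matrix(sample(c(0:2, NA), 120, TRUE), 1, 120,
                    dimnames = list("a", NULL))
    g3 <- toy_geno(codes)
    runs <- detect_roh(g3)
    hom <- !is.na(codes[1, ]) & codes[1, ] != 1L
    oracle <- quadratic_roh(hom)
    expect_equal(nrow(runs), length(oracle))
    if (length(oracle)) {
      om <- do.call(rbind, oracle)
      expect_equal(runs$start_idx, unname(om[, "start"]))
      expect_equal(runs$end_idx, unname(om[, "end"]))
    }
  }
  # linear-scan oracle on longer strings, with chromosome splits
  set.seed(13)
  codes <- matrix(sample(c(0L, 1L, 2L), 2000, TRUE, prob = c(.4, .2, .4)),
                  2, 1000, dimnames = list(c("a", "b"), NULL))
  g4 <- toy_geno(codes, chr = rep(c("1", "2"), each = 500))
  runs <- detect_roh(g4)
  for (an in c("a", "b")) {
    for (ch in c("1", "2")) {
      cols <- which(g4$map$chr == ch)
      hom <- g4$codes[an, cols] != 1L
      oracle <- brute_force_roh(hom)
      got <- runs[runs$animal == an & runs$chr == ch, ]
      expect_equal(nrow(got), length(oracle))
      expect_equal(got$start_idx - min(cols) + 1L,
                   unname(vapply(oracle, `[[`, integer(1), "start")))
    }
  }
  # runs never span chromosomes
  g5 <- toy_geno(matrix(2L, 1, 20, dimnames = list("a", NULL)),
                 chr = rep(c("1", "2"), each = 10))
  expect_equal(detect_roh(g5)$n_snps, c(10L, 10L))
})

test_that("roh_f counts SNPs inside qualifying runs", {
  codes <- matrix(1L, 1, 100, dimnames = list("a", NULL))
  codes[1, 11:70] <- 2L # one 60-SNP run
  g <- toy_geno(codes)
  runs <- detect_roh(g)
  expect_equal(roh_f(runs, 100, 50)$roh_f, 0.6)
  expect_equal(roh_f(runs, 100, 70)$roh_f, 0)
  expect_error(roh_f(runs, 100, 0), "n must be")
  # multi-run case against per-position indicator counting
  set.seed(4)
  codes2 <- matrix(sample(c(0L, 1L, 2L), 500, TRUE, prob = c(.45, .1, .45)),
                   1, 500, dimnames = list("a", NULL))
  g2 <- toy_geno(codes2)
  runs2 <- detect_roh(g2)
  for (n in c(1, 5, 20)) {
    covered <- rep(FALSE, 500)
    for (r in seq_len(nrow(runs2))) {
      if (runs2$n_snps[r] >= n) covered[runs2$start_idx[r]:runs2$end_idx[r]] <- TRUE
    }
    expect_equal(roh_f(runs2, 500, n)$roh_f, mean(covered))
  }
})

test_that("roh_f is monotone non-increasing in n and roh_f(1) = homozygosity", {
  set.seed(31)
  codes <- matrix(sample(c(0L, 1L, 2L), 3000, TRUE, prob = c(.4, .2, .4)),
                  5, 600, dimnames = list(sprintf("a%d", 1:5), NULL))
  g <- toy_geno(codes, chr = rep(c("1", "2"), each = 300))
  runs <- detect_roh(g)
  grid <- c(1, seq(5, 100, 5))
  rf <- roh_f(runs, 600, grid)
  hom <- homozygosity_proportion(g)
  for (an in rownames(codes)) {
    vals <- rf$roh_f[rf$animal == an][order(grid)]
    expect_true(all(diff(vals[order(sort(grid))]) <= 1e-12))
    expect_equal(rf$roh_f[rf$animal == an & rf$n == 1],
                 hom$homozygosity[hom$animal == an])
  }
})

test_that("roh_indicator window_start equals a direct slice check", {
  set.seed(9)
  codes <- matrix(sample(c(0L, 1L, 2L), 800, TRUE, prob = c(.45, .1, .45)),
                  2, 400, dimnames = list(c("a", "b"), NULL))
  g <- toy_geno(codes, chr = rep(c("1", "2"), each = 200))
  n <- 25
  ind <- roh_indicator(g, n, "window_start")
  for (an in c("a", "b")) {
    for (i in seq_len(400)) {
      ch <- g$map$chr[i]
      last <- max(which(g$map$chr == ch))
      if (i + n - 1 > last) {
        expect_true(is.na(ind[an, i]))
      } else {
        slice <- g$codes[an, i:(i + n - 1)]
        expect_equal(ind[an, i],
                     as.integer(all(!is.na(slice) & slice != 1L)))
      }
    }
  }
})

test_that("roh_indicator covering marks positions inside long maximal runs", {
  codes <- matrix(1L, 1, 100, dimnames = list("a", NULL))
  codes[1, 10:49] <- 0L  # 40-SNP run
  codes[1, 60:69] <- 2L  # 10-SNP run
  g <- toy_geno(codes)
  ind <- roh_indicator(g, 20, "covering")
  expect_equal(unname(ind[1, 30]), 1L)
  expect_equal(unname(ind[1, 65]), 0L) # run too short
  expect_equal(unname(ind[1, 5]), 0L)
  # fully homozygous chromosome: both modes mark every (valid) position
  gh <- toy_geno(matrix(2L, 1, 60, dimnames = list("a", NULL)))
  expect_true(all(roh_indicator(gh, 30, "covering") == 1L))
  iw <- roh_indicator(gh, 30, "window_start")
  expect_true(all(iw[1, 1:31] == 1L))
  expect_true(all(is.na(iw[1, 32:60])))
  # heterozygote at the position -> 0 in both modes
  gx <- toy_geno(matrix(c(1L, rep(2L, 59)), 1, 60, dimnames = list("a", NULL)))
  expect_equal(unname(roh_indicator(gx, 30, "covering")[1, 1]), 0L)
  expect_equal(unname(roh_indicator(gx, 30, "window_start")[1, 1]), 0L)
})

test_that("opposing homozygotes count and threshold flag", {
  g <- toy_geno(rbind(child = rep(0L, 5), parent = rep(2L, 5),
                      het = rep(1L, 5)))
  oh <- opposing_homozygotes(g, "child", "parent")
  expect_equal(oh$n_opposing, 5L)
  expect_false(oh$incompatible) # 5 <= 20
  expect_equal(opposing_homozygotes(g, "het", "parent")$n_opposing, 0L)
  expect_true(opposing_homozygotes(g, "child", "parent", threshold = 3)$incompatible)
})

test_that("true trios pass the opposing-homozygote check despite genotyping error", {
  # parent-offspring pairs at 45k SNPs with 0.1% genotyping error
  # (an error misreads one of the two alleles, so 0.05% per allele)
  set.seed(77)
  n_rep <- 20
  counts <- integer(n_rep)
  for (r in seq_len(n_rep)) {
    m <- 45000
    p <- runif(m, 0.05, 0.5)
    sire <- rbinom(m, 1, p) + rbinom(m, 1, p)
    dam <- rbinom(m, 1, p) + rbinom(m, 1, p)
    from_s <- ifelse(sire == 1, rbinom(m, 1, 0.5), sire / 2)
    from_d <- ifelse(dam == 1, rbinom(m, 1, 0.5), dam / 2)
    child <- from_s + from_d
    err <- function(gt) {
      a1 <- ifelse(gt == 1, rbinom(m, 1, 0.5), gt / 2)
      a2 <- gt - a1
      f1 <- rbinom(m, 1, 0.0005); f2 <- rbinom(m, 1, 0.0005)
      abs(a1 - f1) + abs(a2 - f2)
    }
    codes <- rbind(child = err(child), sire = err(sire))
    g <- toy_geno(codes)
    counts[r] <- opposing_homozygotes(g, "child", "sire")$n_opposing
  }
  expect_gte(mean(counts <= 20), 0.99)
  # unrelated pair for contrast: opposing homozygotes are abundant
  set.seed(78)
  m <- 5000
  p <- runif(m, 0.05, 0.5)
  un <- rbind(x = rbinom(m, 2, p), y = rbinom(m, 2, p))
  expect_true(opposing_homozygotes(toy_geno(un), "x", "y")$incompatible)
})

test_that("measure correlations recover exact special cases", {
  m <- tibble::tibble(animal = sprintf("a%d", 1:10), x = rnorm(10))
  m$dup <- m$x
  m$neg <- -m$x
  cors <- measure_correlations(m)
  expect_equal(cors["x", "dup"], 1)
  expect_equal(cors["x", "neg"], -1)
  m$const <- 1
  expect_warning(cors2 <- measure_correlations(m), "constant")
  expect_true(is.na(cors2["x", "const"]))
  expect_error(measure_correlations(m[1:2, ]), "at least 3")
})

test_that("inbreeding_measures assembles per-animal columns consistently", {
  set.seed(44)
  ped <- random_pedigree(60, seed = 44)
  codes <- matrix(sample(c(0L, 1L, 2L), 60 * 200, TRUE), 60, 200,
                  dimnames = list(ped$animal, NULL))
  g <- toy_geno(codes, chr = rep("1", 200))
  meas <- inbreeding_measures(ped, g, n_grid = c(1, 10, 50))
  expect_setequal(names(meas), c("animal", "f_ped", "grm_f", "homozygosity",
                                 "roh_f_1", "roh_f_10", "roh_f_50"))
  expect_equal(meas$roh_f_1, meas$homozygosity, tolerance = 1e-12)
  expect_true(all(meas$roh_f_10 >= meas$roh_f_50 - 1e-12))
})
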