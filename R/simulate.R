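#' Simulation configuration
#'
#' Defines a multi-generation livestock breeding scheme with a small sire
#' pool (so pedigree inbreeding accumulates by drift), optional forced
#' close matings, a SNP map with gene dropping under a Haldane
#' recombination model, and a repeated-records phenotype model with
#' genome-wide inbreeding depression plus locus-specific recessive effects
#' triggered by autozygosity.
#'
#' Defaults emulate a dairy-cow dataset: phenotypic scale of lactation milk
#' yield in litres, heritability 0.25, repeatability 0.40, genome-wide
#' depression of -25 L per 1% realised inbreeding.
#'
#' @param n_founders Founder animals (half male, half female).
#' @param n_generations Discrete generations after the founders.
#' @param n_sires_per_generation Males sampled as sires each generation.
#' @param n_offspring_per_generation Offspring born each generation; a
#'   vector is recycled across generations (e.g. to grow the population in
#'   the phenotyped generations only). Offspring are produced in
#'   opposite-sex pairs per mating, so odd counts are rounded up.
#' @param full_sib_fraction Fraction of each generation's matings (from
#'   generation 2 on) that pair opposite-sex full sibs of the previous
#'   generation, emulating sustained recent close inbreeding with long
#'   runs of homozygosity; 0 = drift only.
#' @param forced_matings List with counts `full_sib` and
#'   `parent_offspring` injected each generation (once eligible pairs
#'   exist).
#' @param n_chromosomes,snps_per_chromosome,chromosome_length_cM Genome
#'   layout; SNPs are evenly spaced, 1 cM = 1 Mb.
#' @param founder_maf_range Founder allele frequencies are drawn uniformly
#'   on this interval per SNP.
#' @param qtl Optional tibble/data frame with columns `chr`, `snp_index`
#'   (index within the chromosome) and `effect` (trait units added to every
#'   record of an animal autozygous at that locus).
#' @param depression_per_unit_F Trait units per unit of true genome-wide
#'   IBD proportion (default -2500, i.e. -25 per 1%).
#' @param mu Trait mean.
#' @param b1_age Fixed regression on age at first calving (trait units per
#'   month).
#' @param n_hys Number of herd-year-season levels.
#' @param fixed_effect_sds Named numeric: SDs of the `hys`, `parity` and
#'   `month` effect distributions (trait units).
#' @param vc List with `sigma2_a`, `sigma2_pe`, `sigma2_e` (trait units^2).
#' @param records_per_cow Lactation records per phenotyped cow.
#' @param n_cows Phenotyped cows (sampled from females of the last
#'   `phenotyped_generations` generations with known parents); `NULL` =
#'   all eligible.
#' @param phenotyped_generations How many final generations contribute
#'   phenotyped cows (default 3).
#' @param geno_error_rate Per-allele genotyping error (flip) rate.
#' @param geno_missing_rate Per-genotype missing rate.
#' @param base_year Birth year of the founder generation.
#' @param seed Mandatory integer seed; every stage derives its own stream
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 200,
                       n_generations = 8,
                       n_sires_per_generation = 5,
                       n_offspring_per_generation = n_founders,
                       full_sib_fraction = 0,
                       forced_matings = list(full_sib = 2, parent_offspring = 1),
                       n_chromosomes = 2,
                       snps_per_chromosome = 1000,
                       chromosome_length_cM = 100,
                       founder_maf_range = c(0.05, 0.5),
                       qtl = NULL,
                       depression_per_unit_F = -2500,
                       mu = 5200,
                       b1_age = 10,
                       n_hys = 25,
                       fixed_effect_sds = c(hys = 250, parity = 150, month = 60),
                       vc = list(sigma2_a = 0.25 * 1635^2,
                                 sigma2_pe = 0.15 * 1635^2,
                                 sigma2_e = 0.60 * 1635^2),
                       records_per_cow = 3,
                       n_cows = NULL,
                       phenotyped_generations = 3,
                       geno_error_rate = 0,
                       geno_missing_rate = 0,
                       base_year = 2000,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  counts <- c(cfg$n_founders, cfg$n_generations, cfg$n_sires_per_generation,
              cfg$n_offspring_per_generation, cfg$n_chromosomes,
              cfg$snps_per_chromosome, cfg$records_per_cow)
  stopifnot(all(counts > 0), cfg$chromosome_length_cM >= 0)
  structure(cfg, class = "sim_config")
}

# independent deterministic sub-stream per simulation stage
sim_seed <- function(cfg, stage) {
  offs <- c(pedigree = 11L, genes = 23L, phenotypes = 37L)
  (as.integer(cfg$seed) * 97L + offs[[stage]]) %% .Machine$integer.max
}

#' Simulate a discrete-generation breeding pedigree
#'
#' Founders form generation 0. Every mating in later generations produces
#' an opposite-sex pair of offspring, so full-sib pairs are always
#' available for close matings. A configurable fraction of matings
#' (`full_sib_fraction`) pairs full sibs of the previous generation -
#' sustained over generations this compounds recent inbreeding and
#' produces long runs of homozygosity. The remaining matings draw the sire
#' from a small pool of previous-generation males (drift inbreeding) and
#' the dam from previous-generation females. Forced `full_sib` /
#' `parent_offspring` matings are injected on top where eligible pairs
#' exist. Birth year is `base_year + generation`.
#'
#' @param cfg A [sim_config].
#' @return A [pedigree] with an extra `generation` column.
#' @export
simulate_pedigree <- function(cfg) {
  set.seed(sim_seed(cfg, "pedigree"))
  nf <- cfg$n_founders
  rec <- tibble::tibble(
    animal = sprintf("G0_%04d", seq_len(nf)),
    sire = NA_character_, dam = NA_character_,
    birth_year = cfg$base_year,
    sex = rep(c("M", "F"), length.out = nf),
    generation = 0L
  )
  prev <- rec
  n_off_gen <- rep_len(cfg$n_offspring_per_generation, cfg$n_generations)
  sib_pairs <- NULL # 2-column matrix (M, F) of full-sib pairs, previous gen
  for (g in seq_len(cfg$n_generations)) {
    males <- prev$animal[prev$sex == "M"]
    females <- prev$animal[prev$sex == "F"]
    if (!length(males)) stop("sire pool empty at generation ", g, call. = FALSE)
    n_mating <- ceiling(n_off_gen[g] / 2)
    sires_pool <- sample(males, min(cfg$n_sires_per_generation, length(males)))
    mat_s <- sample(sires_pool, n_mating, replace = TRUE)
    mat_d <- sample(females, n_mating, replace = TRUE)
    # full-sib matings: a fraction of matings plus any forced count
    n_fs_want <- floor(cfg$full_sib_fraction * n_mating) +
      (cfg$forced_matings$full_sib %||% 0)
    n_fs <- min(n_fs_want, if (is.null(sib_pairs)) 0L else nrow(sib_pairs))
    if (n_fs > 0) {
      pick <- sample.int(nrow(sib_pairs), n_fs)
      mat_s[seq_len(n_fs)] <- sib_pairs[pick, 1L]
      mat_d[seq_len(n_fs)] <- sib_pairs[pick, 2L]
    }
    n_po <- cfg$forced_matings$parent_offspring %||% 0
    if (n_po > 0 && n_fs + n_po <= n_mating) {
      elig <- prev[prev$sex == "F" & !is.na(prev$sire), ]
      if (nrow(elig)) {
        elig <- elig[sample.int(nrow(elig), min(n_po, nrow(elig))), ]
        rows <- n_fs + seq_len(nrow(elig))
        mat_s[rows] <- elig$sire
        mat_d[rows] <- elig$animal
      }
    }
    ids <- sprintf("G%d_%04d", g, seq_len(2L * n_mating))
    gen <- tibble::tibble(
      animal = ids,
      sire = rep(mat_s, each = 2L),
      dam = rep(mat_d, each = 2L),
      birth_year = cfg$base_year + g,
      sex = rep(c("M", "F"), n_mating),
      generation = g
    )
    sib_pairs <- cbind(ids[seq(1L, 2L * n_mating, 2L)],
                       ids[seq(2L, 2L * n_mating, 2L)])
    rec <- dplyr::bind_rows(rec, gen)
    prev <- gen
  }
  ped <- pedigree(rec[, c("animal", "sire", "dam", "birth_year", "sex")])
  ped$generation <- rec$generation[match(ped$animal, rec$animal)]
  ped
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gene dropping with recombination and exact IBD tracking
#'
#' Founders receive two gametes per chromosome with alleles drawn at
#' per-SNP founder frequencies and a unique founder-gamete label per
#' gamete. Every descendant inherits, from each parent, a recombinant of
#' the parent's two gametes: crossover counts are Poisson with mean
#' `chromosome_length_cM / 100` (Haldane model, no interference), crossover
#' positions uniform along the chromosome. Genotype code = allele sum; a
#' locus is autozygous when both gamete labels coincide, giving the exact
#' realised IBD proportion per animal.
#'
#' With `geno_error_rate > 0` each allele flips independently at that rate
#' (truth labels are unaffected); `geno_missing_rate` blanks genotypes at
#' random.
#'
#' @param ped A [pedigree] from [simulate_pedigree()] (any pedigree works).
#' @param cfg A [sim_config].
#' @return A list of class `gene_drop`: `genotypes` (a [geno_matrix]),
#'   `truth` (list with per-animal `ibd` tibble (`animal`,
#'   `true_ibd_proportion`), the full `autozygous` logical matrix, and a
#'   `qtl_status` tibble when `cfg$qtl` is set), and `founder_freq` (the
#'   drawn founder allele frequencies).
#' @export
drop_genes <- function(ped, cfg) {
  set.seed(sim_seed(cfg, "genes"))
  n <- nrow(ped)
  pidx <- ped_parent_idx(ped)
  n_chr <- cfg$n_chromosomes
  n_snp <- cfg$snps_per_chromosome
  len <- cfg$chromosome_length_cM
  cm_pos <- seq(0, len, length.out = n_snp + 1L)[-1L] - len / (2 * n_snp)
  if (len == 0) cm_pos <- rep(0, n_snp)
  maf <- matrix(stats::runif(n_chr * n_snp, cfg$founder_maf_range[1],
                             cfg$founder_maf_range[2]), n_chr, n_snp)
  codes <- matrix(NA_integer_, n, n_chr * n_snp)
  auto <- matrix(NA, n, n_chr * n_snp)
  next_label <- 1L
  for (ch in seq_len(n_chr)) {
    a1 <- a2 <- matrix(0L, n, n_snp)   # allele content of the two gametes
    l1 <- l2 <- matrix(0L, n, n_snp)   # founder-gamete labels
    meiosis <- function(al_a, al_b, lb_a, lb_b) {
      k <- stats::rpois(1, len / 100)
      phase0 <- sample.int(2L, 1L) - 1L
      if (k == 0L) {
        if (phase0 == 0L) list(a = al_a, l = lb_a) else list(a = al_b, l = lb_b)
      } else {
        xo <- sort(stats::runif(k, 0, len))
        phase <- (phase0 + findInterval(cm_pos, xo)) %% 2L
        pick <- phase == 0L
        list(a = ifelse(pick, al_a, al_b), l = ifelse(pick, lb_a, lb_b))
      }
    }
    for (i in seq_len(n)) {
      si <- pidx$s[i]
      di <- pidx$d[i]
      for (side in 1:2) {
        p <- if (side == 1) si else di
        if (is.na(p)) { # founder gamete
          al <- as.integer(stats::rbinom(n_snp, 1L, maf[ch, ]))
          lb <- rep(next_label, n_snp)
          next_label <- next_label + 1L
        } else {
          gm <- meiosis(a1[p, ], a2[p, ], l1[p, ], l2[p, ])
          al <- gm$a
          lb <- gm$l
        }
        if (side == 1) { a1[i, ] <- al; l1[i, ] <- lb }
        else { a2[i, ] <- al; l2[i, ] <- lb }
      }
    }
    cols <- (ch - 1L) * n_snp + seq_len(n_snp)
    g12 <- a1 + a2
    if (cfg$geno_error_rate > 0) {
      flip1 <- matrix(stats::runif(n * n_snp) < cfg$geno_error_rate, n, n_snp)
      flip2 <- matrix(stats::runif(n * n_snp) < cfg$geno_error_rate, n, n_snp)
      g12 <- (a1 + flip1) %% 2L + (a2 + flip2) %% 2L
    }
    codes[, cols] <- g12
    auto[, cols] <- l1 == l2
  }
  if (cfg$geno_missing_rate > 0) {
    codes[matrix(stats::runif(length(codes)) < cfg$geno_missing_rate,
                 nrow(codes))] <- NA_integer_
  }
  rownames(codes) <- ped$animal
  # 1 cM = 1 Mb; index offset keeps positions strictly increasing even for
  # degenerate zero-length maps
  bp <- as.integer(round(cm_pos * 1e6)) + seq_len(n_snp)
  map <- tibble::tibble(
    snp_id = sprintf("snp_%d_%04d", rep(seq_len(n_chr), each = n_snp),
                     rep(seq_len(n_snp), n_chr)),
    chr = as.character(rep(seq_len(n_chr), each = n_snp)),
    pos_bp = rep(bp, n_chr)
  )
  truth_ibd <- tibble::tibble(animal = ped$animal,
                              true_ibd_proportion = rowMeans(auto))
  qtl_status <- NULL
  if (!is.null(cfg$qtl)) {
    q <- tibble::as_tibble(cfg$qtl)
    stopifnot(all(c("chr", "snp_index", "effect") %in% names(q)))
    if (any(q$snp_index < 1 | q$snp_index > n_snp) ||
        any(q$chr < 1 | q$chr > n_chr)) {
      stop("QTL index outside the SNP map", call. = FALSE)
    }
    q$col <- (q$chr - 1L) * n_snp + q$snp_index
    qtl_status <- tibble::as_tibble(auto[, q$col, drop = FALSE],
                                    .name_repair = "minimal")
    names(qtl_status) <- sprintf("qtl_%d_%d", q$chr, q$snp_index)
    qtl_status <- dplyr::bind_cols(tibble::tibble(animal = ped$animal),
                                   qtl_status)
  }
  g <- geno_matrix(codes, map)
  structure(list(genotypes = g,
                 truth = list(ibd = truth_ibd, autozygous = auto,
                              qtl_status = qtl_status, qtl = cfg$qtl),
                 founder_freq = maf),
            class = "gene_drop")
}

#' Simulate repeated-records phenotypes with inbreeding depression
#'
#' Phenotypes follow the animal-model data-generating process:
#' `y = mu + hys + parity + month + b1 * age + d * trueIBD +
#' sum(QTL effects when autozygous) + u + pe + e`, where `u` is a breeding
#' value drawn consistently with the pedigree (founder draws plus
#' Mendelian-sampling deviations scaled by parental inbreeding), `pe` is a
#' per-cow permanent-environment effect and `e` a per-record residual.
#' Herd-year-season, parity and month effects are draws from normal
#' distributions with configured SDs; each record samples an HYS level and
#' a calving month, parities run 1, 2, ....
#'
#' @param ped A [pedigree] (with `generation` column, as from
#'   [simulate_pedigree()]).
#' @param truth The `truth` element of a [drop_genes()] result (or `NULL`
#'   for no genomic depression/QTL terms).
#' @param cfg A [sim_config].
#' @return A list: `phenotypes` (tibble with `cow`, `trait`, `value`,
#'   `hys`, `parity`, `month`, `age_fc`), `breeding_values` (tibble
#'   `animal`, `u`), and `cows` (ids of the phenotyped cows).
#' @export
simulate_phenotypes <- function(ped, truth, cfg) {
  set.seed(sim_seed(cfg, "phenotypes"))
  n <- nrow(ped)
  pidx <- ped_parent_idx(ped)
  f <- inbreeding_ml(ped)$F
  # breeding values down the pedigree
  sa <- sqrt(cfg$vc$sigma2_a)
  u <- numeric(n)
  for (i in seq_len(n)) {
    si <- pidx$s[i]
    di <- pidx$d[i]
    pm <- 0.5 * ((if (!is.na(si)) u[si] else 0) + (if (!is.na(di)) u[di] else 0))
    mv <- mendelian_variance(f, si, di)
    u[i] <- pm + stats::rnorm(1, 0, sa * sqrt(mv))
  }
  gen <- ped$generation %||% rep(0L, n)
  min_gen <- max(0L, cfg$n_generations - cfg$phenotyped_generations + 1L)
  elig <- ped$animal[ped$sex == "F" & gen >= min_gen &
                       !is.na(ped$sire) & !is.na(ped$dam)]
  if (!length(elig)) stop("no phenotype-eligible females", call. = FALSE)
  cows <- if (is.null(cfg$n_cows)) elig else {
    if (length(elig) < cfg$n_cows) {
      stop("only ", length(elig), " eligible cows; n_cows = ", cfg$n_cows,
           call. = FALSE)
    }
    sample(elig, cfg$n_cows)
  }
  k <- cfg$records_per_cow
  hys_eff <- stats::rnorm(cfg$n_hys, 0, cfg$fixed_effect_sds[["hys"]])
  par_eff <- stats::rnorm(k, 0, cfg$fixed_effect_sds[["parity"]])
  mon_eff <- stats::rnorm(12, 0, cfg$fixed_effect_sds[["month"]])
  nc <- length(cows)
  ci <- match(cows, ped$animal)
  ibd <- if (!is.null(truth)) {
    truth$ibd$true_ibd_proportion[match(cows, truth$ibd$animal)]
  } else rep(0, nc)
  qtl_term <- rep(0, nc)
  if (!is.null(truth) && !is.null(truth$qtl_status)) {
    qs <- truth$qtl_status[match(cows, truth$qtl_status$animal), -1,
                           drop = FALSE]
    qtl_term <- as.numeric(as.matrix(qs) %*% tibble::as_tibble(truth$qtl)$effect)
  }
  pe <- stats::rnorm(nc, 0, sqrt(cfg$vc$sigma2_pe))
  age <- stats::rnorm(nc, 26, 2)
  rec_cow <- rep(seq_len(nc), each = k)
  parity <- rep(seq_len(k), nc)
  hys <- sample.int(cfg$n_hys, nc * k, replace = TRUE)
  month <- sample.int(12L, nc * k, replace = TRUE)
  e <- stats::rnorm(nc * k, 0, sqrt(cfg$vc$sigma2_e))
  y <- cfg$mu + hys_eff[hys] + par_eff[parity] + mon_eff[month] +
    cfg$b1_age * age[rec_cow] + cfg$depression_per_unit_F * ibd[rec_cow] +
    qtl_term[rec_cow] + u[ci][rec_cow] + pe[rec_cow] + e
  phen <- tibble::tibble(cow = cows[rec_cow], trait = "milk_L", value = y,
                         hys = hys, parity = parity, month = month,
                         age_fc = age[rec_cow])
  list(phenotypes = phen,
       breeding_values = tibble::tibble(animal = ped$animal, u = u),
       cows = cows)
}

#' Simulate a complete herd dataset
#'
#' Runs [simulate_pedigree()], [drop_genes()] and [simulate_phenotypes()]
#' under one configuration. The same seed reproduces every component
#' exactly.
#'
#' @param cfg A [sim_config].
#' @return List of class `sim_herd`: `pedigree`, `genotypes`, `truth`,
#'   `phenotypes`, `breeding_values`, `cows`, `config`.
#' @export
simulate_herd <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  gd <- drop_genes(ped, cfg)
  ph <- simulate_phenotypes(ped, gd$truth, cfg)
  structure(list(pedigree = ped, genotypes = gd$genotypes, truth = gd$truth,
                 founder_freq = gd$founder_freq,
                 phenotypes = ph$phenotypes,
                 breeding_values = ph$breeding_values,
                 cows = ph$cows, config = cfg),
            class = "sim_herd")
}
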