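# Synthetic-data generator. Emulates the statistical structure of sexed
# blastocyst / donor-cell FPKM matrices: balanced autosomes, female-specific
# X-linked upregulation with group-specific magnitude carried by a subset of
# "responder" genes, XIST restricted to females, Y genes restricted to males,
# per-blastocyst variability of female X activity, and paired IT/TE splits.

# Per-group responder-fold shape constants of the bundled profile.
# A responder gene's female:male fold is drawn as
#   up (prob 1 - male_fraction):
#     capped_exp:       log2 fold = up_top - Exponential(up_rate)
#     truncated_normal: log2 fold ~ Normal(up_mean, up_sd) truncated at 0
#   down (prob male_fraction):   log2 fold = -Normal(down_mean, down_sd)
# i.e. a left-skewed reactivation distribution (bounded above for the
# capped-exponential form), plus a minority of female-repressed (male-high)
# genes. The shapes are calibration data: fractions and shape parameters
# were fit (moment matching plus simulation) so that, together with
# `x_upregulation`, the aggregate F:M fold and the F:M > 1 / > 2 gene
# proportions are matched simultaneously; a single global fold cannot match
# both.
RESPONDER_SHAPES <- list(
  IVF   = list(fraction = 0.600, male_fraction = 0.06, up_dist = "capped_exp",
               up_top = 1.60, up_rate = 2.40, down_mean = 0.86, down_sd = 0.40),
  SCNT  = list(fraction = 0.522, male_fraction = 0.18, up_dist = "capped_exp",
               up_top = 1.40, up_rate = 4.66, down_mean = 0.86, down_sd = 0.40),
  SHAM  = list(fraction = 0.639, male_fraction = 0.06, up_dist = "truncated_normal",
               up_mean = 1.00, up_sd = 0.75, down_mean = 0.86, down_sd = 0.40),
  DONOR = list(fraction = 0.000, male_fraction = 0.00, up_dist = "capped_exp",
               up_top = 1.00, up_rate = 10.0, down_mean = 0.86, down_sd = 0.40)
)

# Expected fold of a responder shape (analytic; used to rescale folds so the
# realised aggregate matches x_upregulation exactly in expectation).
shape_mean_fold <- function(s) {
  ln2 <- log(2)
  if (s$fraction == 0) return(1)
  e_up <- if (identical(s$up_dist, "truncated_normal")) {
    # E[2^X] for X ~ N(m, sd) truncated below at 0
    m <- s$up_mean; sd <- s$up_sd
    a <- -m / sd
    2^m * exp((sd * ln2)^2 / 2) *
      stats::pnorm(sd * ln2 - a) / stats::pnorm(-a)
  } else {
    2^s$up_top * s$up_rate / (s$up_rate + ln2)
  }
  e_dn <- 2^(-s$down_mean) * exp((s$down_sd * ln2)^2 / 2)
  1 + s$fraction * ((1 - s$male_fraction) * e_up + s$male_fraction * e_dn - 1)
}

#' Build a simulation configuration
#'
#' All parameters of the generator with their bundled defaults. The defaults
#' constitute the calibrated profile (see [paper_profile()]); [null_profile()]
#' switches every sex effect off.
#'
#' @param seed integer seed; mandatory, the generator is fully deterministic
#'   given the configuration
#' @param n_autosomal_genes,n_x_genes,n_y_genes,n_autosomes gene and
#'   chromosome counts
#' @param autosome_length_bp,x_length_bp,y_length_bp chromosome lengths used
#'   for uniform gene placement
#' @param samples_per_cell samples per (sex, group) cell
#' @param baseline_log2_mean,baseline_log2_sd log2-normal per-gene baseline
#'   FPKM distribution
#' @param biological_noise_sd per-sample multiplicative noise, log2 units
#' @param sample_scale_sd per-sample global scale jitter (library-size
#'   normalisation imperfection), log2 units
#' @param x_activity_sd per-blastocyst female X-activity variability, log2
#'   units; applied to female X genes of embryo groups only
#' @param dropout_rate probability that a low-expression measurement is
#'   zeroed; `dropout_quantile` defines "low" (per-sample quantile of
#'   positive values)
#' @param dropout_quantile see `dropout_rate`
#' @param x_upregulation named fold per group: aggregate female:male X-linked
#'   expression ratio the generator targets
#' @param responder_shapes per-group responder-fold shape constants (see
#'   source); calibration data, versioned with the package
#' @param male_x_baseline_factor scaling of single-copy X (and Y) genes
#'   relative to autosomes; calibrated so the male X:A ratio is ~0.49
#' @param xist_fpkm female XIST expression level per group (FPKM)
#' @param donor_sex_divergence_sd symmetric per-gene log2 sex divergence of
#'   donor fibroblast X genes (clonal XCI skewing between the two lines)
#' @param lineage_effect IT:TE fold applied to X genes of IT parts
#'   (1 = no imprinting)
#' @param icm_fraction ICM fraction of the IT part by cell number; used by
#'   [imprinted_lineage_effect()] to express imprinting as a diluted fold
#' @param split_noise_sd measurement noise between the two parts of a split
#'   embryo, log2 units
#' @param embryo_noise_sd per-embryo biological noise in lineage datasets,
#'   log2 units
#' @param testes_gene_count size of the simulated testes-specific X set
#' @param testes_baseline_log2_mean,testes_baseline_log2_sd baseline of the
#'   (somatically silenced) testes-specific genes
#' @param testes_derepression_fold female-blastocyst derepression fold of the
#'   testes-specific set
#' @return object of class `xdg_sim_config`
#' @export
simulation_config <- function(seed,
                              n_autosomal_genes = 12000,
                              n_x_genes = 700,
                              n_y_genes = 30,
                              n_autosomes = 29,
                              autosome_length_bp = 1.2e8,
                              x_length_bp = 1.5e8,
                              y_length_bp = 4.3e7,
                              samples_per_cell = 6,
                              baseline_log2_mean = 2.0,
                              baseline_log2_sd = 2.0,
                              biological_noise_sd = 0.35,
                              sample_scale_sd = 0.09,
                              x_activity_sd = 0.40,
                              dropout_rate = 0.05,
                              dropout_quantile = 0.25,
                              x_upregulation = c(IVF = 1.8, SCNT = 1.5,
                                                 SHAM = 1.9, DONOR = 1.0),
                              responder_shapes = RESPONDER_SHAPES,
                              male_x_baseline_factor = 0.479,
                              xist_fpkm = c(IVF = 1000, SCNT = 575,
                                            SHAM = 1000, DONOR = 610),
                              donor_sex_divergence_sd = 1.41,
                              lineage_effect = 1.0,
                              icm_fraction = 0.5,
                              split_noise_sd = 0.10,
                              embryo_noise_sd = 0.35,
                              testes_gene_count = 29,
                              testes_baseline_log2_mean = -3.6,
                              testes_baseline_log2_sd = 1,
                              testes_derepression_fold = 4) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  stopifnot(all(cfg$x_upregulation > 0),
            cfg$male_x_baseline_factor > 0,
            cfg$dropout_rate >= 0, cfg$dropout_rate < 1,
            cfg$icm_fraction >= 0, cfg$icm_fraction <= 1,
            all(vapply(cfg$responder_shapes, function(s)
              s$fraction >= 0 && s$fraction <= 1 &&
              s$male_fraction >= 0 && s$male_fraction <= 1, TRUE)))
  structure(cfg, class = "xdg_sim_config")
}

#' The bundled calibrated simulation profile
#'
#' Returns the configuration whose defaults reproduce the headline dosage
#' statistics of sexed bovine blastocyst transcriptomes: aggregate F:M
#' X-linked folds of 1.8/1.5/1.9 (IVF/SCNT/sham), male and female X:A ratios
#' near 0.49 and 1.01 (IVF) and 0.80 (female SCNT), F:M > 1 proportions near
#' 78.7/66.7/78.1/51.2% and F:M > 2 proportions near 46.7/36.2/33.1/24.2%,
#' six samples per sex per group, and no IT/TE lineage effect.
#'
#' @param seed integer seed
#' @param ... overrides passed to [simulation_config()]
#' @return `xdg_sim_config`
#' @export
paper_profile <- function(seed = 1, ...) simulation_config(seed = seed, ...)

#' A configuration with every sex effect switched off
#'
#' Used for type-I error calibration: no X upregulation, no XIST, no female
#' X-activity variability, no donor sex divergence, no testes derepression.
#' Male and female samples are then exchangeable gene-by-gene (Y genes are
#' still male-only and XIST rows are zero everywhere).
#'
#' @param seed integer seed
#' @param ... overrides passed to [simulation_config()]
#' @return `xdg_sim_config`
#' @export
null_profile <- function(seed = 1, ...) {
  simulation_config(seed = seed,
                    x_upregulation = c(IVF = 1, SCNT = 1, SHAM = 1, DONOR = 1),
                    xist_fpkm = c(IVF = 0, SCNT = 0, SHAM = 0, DONOR = 0),
                    x_activity_sd = 0,
                    donor_sex_divergence_sd = 0,
                    testes_derepression_fold = 1,
                    n_y_genes = 0,
                    ...)
}

#' Effective IT:TE fold implied by imprinted inactivation in the TE
#'
#' Under imprinted paternal-X inactivation the TE expresses one X while the
#' reactivated cells express two. The IT part is a mixture of ICM and TE
#' cells, so the observable IT:TE fold is diluted:
#' `(icm_fraction * 2 + (1 - icm_fraction) * 1) / 1` relative X output,
#' i.e. 1.5 at a 1:1 cell ratio rather than 2.
#'
#' @param icm_fraction ICM fraction of the IT part by cell number
#' @return numeric fold to use as `lineage_effect`
#' @export
imprinted_lineage_effect <- function(icm_fraction = 0.5) {
  (icm_fraction * 2 + (1 - icm_fraction)) / 1
}

# ---- internals -------------------------------------------------------------

# Deterministic annotation for a config (assumes RNG already seeded).
sim_annotation <- function(cfg) {
  n_a <- cfg$n_autosomal_genes
  n_x <- cfg$n_x_genes
  n_y <- cfg$n_y_genes
  hk <- DEFAULT_HOUSEKEEPING_SYMBOLS[seq_len(min(length(DEFAULT_HOUSEKEEPING_SYMBOLS), n_a))]
  a_sym <- sprintf("AGENE%05d", seq_len(n_a))
  a_sym[seq_along(hk)] <- hk
  n_tst <- min(cfg$testes_gene_count, max(n_x - 3L, 0L))
  x_sym <- sprintf("XGENE%04d", seq_len(n_x))
  if (n_x >= 1) x_sym[1] <- "XIST"
  if (n_x >= 3) x_sym[2:3] <- DEFAULT_PAR_SYMBOLS
  if (n_tst > 0) x_sym[3L + seq_len(n_tst)] <- sprintf("TSXG%02d", seq_len(n_tst))
  y_sym <- if (n_y > 0) {
    s <- sprintf("YGENE%03d", seq_len(n_y))
    s[seq_len(min(3L, n_y))] <- DEFAULT_MALE_MARKERS[seq_len(min(3L, n_y))]
    s
  } else character()

  chrom <- c(as.character(sample.int(cfg$n_autosomes, n_a, replace = TRUE)),
             rep("X", n_x), rep("Y", n_y))
  len <- ifelse(chrom == "X", cfg$x_length_bp,
                ifelse(chrom == "Y", cfg$y_length_bp, cfg$autosome_length_bp))
  glen <- sample(500:50000, n_a + n_x + n_y, replace = TRUE)
  start <- floor(stats::runif(n_a + n_x + n_y, 1, pmax(len - glen, 2)))
  ann <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n_a + n_x + n_y)),
    symbol = c(a_sym, x_sym, y_sym),
    chrom = chrom,
    start_bp = as.integer(start),
    end_bp = as.integer(start + glen - 1),
    strand = sample(c("+", "-"), n_a + n_x + n_y, replace = TRUE),
    stringsAsFactors = FALSE
  )
  finish_annotation(ann, DEFAULT_PAR_SYMBOLS,
                    if (n_tst > 0) sprintf("TSXG%02d", seq_len(n_tst)) else NULL,
                    hk)
}

# Per-gene baselines; marker and housekeeping genes are forced to robust
# expression so marker-based sexing is reliable, testes-specific genes to the
# somatically silenced regime.
sim_baselines <- function(cfg, ann) {
  n <- nrow(ann)
  b <- 2^stats::rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  tst <- ann$is_testes_specific
  b[tst] <- 2^stats::rnorm(sum(tst), cfg$testes_baseline_log2_mean,
                           cfg$testes_baseline_log2_sd)
  mk <- ann$symbol %in% DEFAULT_MALE_MARKERS
  b[mk] <- 2^stats::rnorm(sum(mk), 4, 0.5)
  hk <- ann$is_housekeeping
  b[hk] <- 2^stats::rnorm(sum(hk), 6, 0.5)
  b
}

# Shared per-gene latents drive responder status across groups, so that
# responder sets are nested (SCNT subset of SHAM subset of IVF at default
# fractions) and fold magnitudes are correlated between groups.
sim_responder_latents <- function(cfg, ann) {
  n <- nrow(ann)
  eligible <- ann$chrom_class == "x_linked" & !ann$is_par & !ann$is_xist &
    !ann$is_testes_specific
  list(eligible = eligible,
       u = stats::runif(n),   # responder membership
       w = stats::runif(n),   # male-high membership among responders
       q = stats::runif(n),   # up-fold magnitude quantile
       z = stats::rnorm(n),   # down-fold magnitude
       e = stats::rnorm(n))   # donor sex-divergence
}

# Female:male fold per gene for one group. Folds are linearly rescaled in
# fold space so the expected aggregate equals x_upregulation[group]; at
# x_upregulation = 1 every fold collapses to exactly 1 (clean null).
sim_group_folds <- function(cfg, ann, lat, group) {
  n <- nrow(ann)
  fold <- rep(1, n)
  shape <- cfg$responder_shapes[[group]]
  target <- unname(cfg$x_upregulation[[group]])
  responder <- rep(FALSE, n)
  if (!is.null(shape) && shape$fraction > 0 && target != 1) {
    responder <- lat$eligible & lat$u < shape$fraction
    male_high <- responder & lat$w < shape$male_fraction
    up <- responder & !male_high
    l2f <- rep(0, n)
    if (identical(shape$up_dist, "truncated_normal")) {
      p0 <- stats::pnorm(0, shape$up_mean, shape$up_sd)
      l2f[up] <- stats::qnorm(p0 + lat$q[up] * (1 - p0),
                              shape$up_mean, shape$up_sd)
    } else {
      l2f[up] <- shape$up_top - stats::qexp(lat$q[up], rate = shape$up_rate)
    }
    l2f[male_high] <- -(shape$down_mean + shape$down_sd * lat$z[male_high])
    s <- (target - 1) / (shape_mean_fold(shape) - 1)
    fold[responder] <- pmax(1 + (2^l2f[responder] - 1) * s, 0.05)
  }
  list(fold = fold, responder = responder)
}

sim_apply_dropout <- function(v, cfg) {
  if (cfg$dropout_rate <= 0) return(v)
  pos <- v[v > 0]
  if (!length(pos)) return(v)
  thr <- stats::quantile(pos, cfg$dropout_quantile, names = FALSE)
  low <- which(v > 0 & v < thr)
  hit <- low[stats::runif(length(low)) < cfg$dropout_rate]
  v[hit] <- 0
  v
}

# One sample's FPKM vector given per-gene expected values.
sim_measure <- function(expected, cfg) {
  v <- expected *
    2^stats::rnorm(length(expected), 0, cfg$biological_noise_sd) *
    2^stats::rnorm(1, 0, cfg$sample_scale_sd)
  sim_apply_dropout(v, cfg)
}

# Expected (noise-free) expression of one (sex, group) cell; the female
# X-activity factor is drawn per sample, so it is applied by the caller.
sim_expected <- function(cfg, ann, base, lat, sex, group, folds) {
  e <- base
  xn <- ann$chrom_class == "x_linked" & !ann$is_par  # single-copy X regime
  yn <- ann$chrom_class == "y_linked"
  e[xn] <- e[xn] * cfg$male_x_baseline_factor
  e[yn] <- if (sex == "male") e[yn] * cfg$male_x_baseline_factor else 0
  e[ann$is_xist] <- if (sex == "female") unname(cfg$xist_fpkm[[group]]) else 0
  if (sex == "female") {
    if (group == "DONOR") {
      div <- lat$eligible
      e[div] <- e[div] * 2^(lat$e[div] * cfg$donor_sex_divergence_sd / 2)
    } else {
      e <- e * folds$fold
      tst <- ann$is_testes_specific
      e[tst] <- e[tst] * cfg$testes_derepression_fold
    }
  } else if (group == "DONOR") {
    div <- lat$eligible
    e[div] <- e[div] * 2^(-lat$e[div] * cfg$donor_sex_divergence_sd / 2)
  }
  e
}

# Mean-one female X-activity factor for one blastocyst.
sim_x_activity <- function(cfg) {
  if (cfg$x_activity_sd <= 0) return(1)
  2^stats::rnorm(1, 0, cfg$x_activity_sd) /
    exp((cfg$x_activity_sd * log(2))^2 / 2)
}

# ---- public generators -----------------------------------------------------

#' Generate a synthetic whole-blastocyst dataset
#'
#' Deterministic given the configuration. Genes are placed uniformly along
#' chromosomes; per-gene baselines are log-normal; female samples of embryo
#' groups carry the group's X-responder folds and XIST expression plus a
#' per-blastocyst X-activity factor; donor-cell sexes diverge symmetrically
#' on X; autosomes have no sex effect; Y genes are male-only.
#'
#' @param config `xdg_sim_config`
#' @param groups subset of `r paste(GROUPS, collapse=", ")`
#' @param sexes subset of male/female
#' @return `xdg_dataset` with attributes `truth` (per-gene per-group
#'   responder flag and true fold) and `sim_config`
#' @export
generate_dataset <- function(config,
                             groups = GROUPS,
                             sexes = SEXES) {
  stopifnot(inherits(config, "xdg_sim_config"),
            length(groups) > 0, length(sexes) > 0)
  groups <- match.arg(groups, GROUPS, several.ok = TRUE)
  sexes <- match.arg(sexes, SEXES, several.ok = TRUE)
  set.seed(config$seed)
  ann <- sim_annotation(config)
  base <- sim_baselines(config, ann)
  lat <- sim_responder_latents(config, ann)
  folds <- lapply(GROUPS, function(g) sim_group_folds(config, ann, lat, g))
  names(folds) <- GROUPS

  cols <- list(); sheet <- list()
  for (g in groups) {
    for (sx in sexes) {
      exp_cell <- sim_expected(config, ann, base, lat, sx, g, folds[[g]])
      for (i in seq_len(config$samples_per_cell)) {
        e <- exp_cell
        if (sx == "female" && g != "DONOR") {
          act <- sim_x_activity(config)
          xg <- ann$chrom_class == "x_linked"
          e[xg] <- e[xg] * act
        }
        id <- sprintf("%s_%s%d", g, toupper(substr(sx, 1, 1)), i)
        cols[[id]] <- sim_measure(e, config)
        sheet[[id]] <- data.frame(sample_id = id, sex = sx, group = g,
                                  lineage = "WHOLE", embryo_id = "",
                                  stringsAsFactors = FALSE)
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- ann$gene_id
  samples <- do.call(rbind, sheet)
  ds <- validate_dataset(ann, m, samples)
  truth <- do.call(rbind, lapply(groups, function(g) {
    data.frame(gene_id = ann$gene_id, group = g,
               responder = folds[[g]]$responder,
               true_fold = folds[[g]]$fold, stringsAsFactors = FALSE)
  }))
  attr(ds, "truth") <- truth
  attr(ds, "sim_config") <- config
  ds
}

#' Generate a paired IT/TE lineage dataset
#'
#' Female embryos of one group are each split into an IT part (ICM plus TE
#' cells) and a TE-only part. The two parts share the embryo's expression
#' (including its X-activity factor) and differ by independent measurement
#' noise; X genes of the IT part are multiplied by `lineage_effect`
#' (1 = no imprinting; see [imprinted_lineage_effect()]).
#'
#' @param config `xdg_sim_config`
#' @param n_embryos number of split embryos (>= 2)
#' @param group embryo group providing the dosage settings
#' @return `xdg_dataset` with paired IT/TE samples
#' @export
generate_lineage_dataset <- function(config, n_embryos = 19, group = "IVF") {
  stopifnot(inherits(config, "xdg_sim_config"), n_embryos >= 2)
  group <- match.arg(group, setdiff(GROUPS, "DONOR"))
  set.seed(config$seed)
  ann <- sim_annotation(config)
  base <- sim_baselines(config, ann)
  lat <- sim_responder_latents(config, ann)
  folds <- sim_group_folds(config, ann, lat, group)
  exp_cell <- sim_expected(config, ann, base, lat, "female", group, folds)
  xg <- ann$chrom_class == "x_linked"

  cols <- list(); sheet <- list()
  for (e_i in seq_len(n_embryos)) {
    emb <- exp_cell * 2^stats::rnorm(length(exp_cell), 0, config$embryo_noise_sd)
    emb[xg] <- emb[xg] * sim_x_activity(config)
    eid <- sprintf("E%02d", e_i)
    for (part in c("IT", "TE")) {
      v <- emb * 2^stats::rnorm(length(emb), 0, config$split_noise_sd) *
        2^stats::rnorm(1, 0, config$sample_scale_sd)
      if (part == "IT") v[xg] <- v[xg] * config$lineage_effect
      v <- sim_apply_dropout(v, config)
      id <- sprintf("%s_%s", eid, part)
      cols[[id]] <- v
      sheet[[id]] <- data.frame(sample_id = id, sex = "female", group = group,
                                lineage = part, embryo_id = eid,
                                stringsAsFactors = FALSE)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- ann$gene_id
  ds <- validate_dataset(ann, m, do.call(rbind, sheet))
  attr(ds, "sim_config") <- config
  ds
}

#' Generate technical replicates of one pooled sample
#'
#' Replicate-concordance QC surface: one biological expression state measured
#' `n_replicates` times with small technical noise, mimicking a pooled-sample
#' library split.
#'
#' @param config `xdg_sim_config`
#' @param n_replicates number of technical replicates
#' @param technical_sd technical noise, log2 units
#' @param sex,group identity of the replicated sample
#' @return `xdg_dataset`
#' @export
generate_replicates <- function(config, n_replicates = 4, technical_sd = 0.05,
                                sex = "female", group = "IVF") {
  stopifnot(inherits(config, "xdg_sim_config"), n_replicates >= 2)
  set.seed(config$seed)
  ann <- sim_annotation(config)
  base <- sim_baselines(config, ann)
  lat <- sim_responder_latents(config, ann)
  folds <- sim_group_folds(config, ann, lat, group)
  e <- sim_expected(config, ann, base, lat, sex, group, folds)
  # one biological draw, shared by all replicates
  e <- e * 2^stats::rnorm(length(e), 0, config$biological_noise_sd)
  cols <- lapply(seq_len(n_replicates), function(i)
    sim_apply_dropout(e * 2^stats::rnorm(length(e), 0, technical_sd), config))
  m <- do.call(cbind, cols)
  dimnames(m) <- list(ann$gene_id, sprintf("REP%d", seq_len(n_replicates)))
  samples <- data.frame(sample_id = colnames(m), sex = sex, group = group,
                        lineage = "WHOLE", embryo_id = "",
                        stringsAsFactors = FALSE)
  validate_dataset(ann, m, samples)
}

#' Write a generated dataset as the three TSV inputs plus ground truth
#'
#' Emits `annotation.tsv`, `expression.tsv`, `samples.tsv` and, when the
#' dataset carries simulation truth, `truth.tsv` (per-gene responder flag and
#' true fold per group) into `dir`.
#'
#' @param dataset `xdg_dataset`
#' @param dir output directory (created if absent)
#' @param params named list recorded in each file's comment header
#' @return `dir`, invisibly
#' @export
write_dataset <- function(dataset, dir, params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- dataset$annotation[, c("gene_id", "symbol", "chrom", "start_bp",
                                "end_bp", "strand")]
  write_xdg_tsv(ann, file.path(dir, "annotation.tsv"), params)
  write_expression(dataset$matrix, file.path(dir, "expression.tsv"), params)
  write_xdg_tsv(dataset$samples, file.path(dir, "samples.tsv"), params)
  if (!is.null(attr(dataset, "truth"))) {
    write_xdg_tsv(attr(dataset, "truth"), file.path(dir, "truth.tsv"), params)
  }
  invisible(dir)
}
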