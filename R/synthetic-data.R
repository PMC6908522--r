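#' Simulation configuration for synthetic multi-study expression data
#'
#' Defines the conditions of the emulated meta-analysis: ten studies split
#' into lung-cancer (LC) and other-lung-disease (LD) classes, group sizes
#' drawn per study from a range, log-normal raw intensities with
#' additive + multiplicative noise, a planted set of consensus
#' differentially expressed genes ("winners") with globally fixed
#' direction, correlated gene blocks for the coexpression stage, and a
#' survival hazard ratio for the survival stage.
#'
#' @param n_lc_studies,n_ld_studies number of LC / LD studies.
#' @param n_genes number of genes per study.
#' @param samples_per_group length-2 integer range; each study draws its
#'   per-group sample size uniformly from this range.
#' @param n_winner_up,n_winner_down planted consensus genes per direction.
#' @param effect_size mean case-vs-control shift of planted genes, in
#'   glog2 units (i.e. a multiplicative `2^effect_size` shift of the raw
#'   baseline).
#' @param winner_penetrance probability that a planted winner is actually
#'   perturbed in a given study.
#' @param n_blocks,block_size correlated gene blocks for coexpression.
#' @param within_block_r,between_block_r target absolute correlations
#'   within and between blocks.
#' @param shared_block_fraction fraction of blocks whose structure is
#'   common to the two conditions of a coexpression pair.
#' @param additive_sd,multiplicative_sd noise model: raw intensity is
#'   `y = background + mu * exp(eta) + eps` with
#'   `eta ~ N(0, multiplicative_sd)` and `eps ~ N(0, additive_sd)`.
#' @param background additive scanner background offset.
#' @param baseline_meanlog,baseline_sdlog log-normal per-gene baseline
#'   intensities `mu`.
#' @param intensity_floor raw intensities are clipped below at this small
#'   positive floor, mimicking scanner output.
#' @param true_hr hazard ratio planted in survival cohorts.
#' @param seed root seed; per-study seeds are derived with [child_seed()].
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_lc_studies = 6, n_ld_studies = 4,
                       n_genes = 2000, samples_per_group = c(10, 60),
                       n_winner_up = 60, n_winner_down = 40,
                       effect_size = 1.5, winner_penetrance = 1.0,
                       n_blocks = 5, block_size = 20,
                       within_block_r = 0.8, between_block_r = 0.1,
                       shared_block_fraction = 0.6,
                       additive_sd = 15, multiplicative_sd = 0.25,
                       background = 20,
                       baseline_meanlog = log(200), baseline_sdlog = 1.1,
                       intensity_floor = 0.5,
                       true_hr = 2.0, seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_lc_studies", "n_ld_studies", "n_genes", "n_winner_up",
              "n_winner_down", "n_blocks", "block_size")
  for (f in counts)
    if (length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]) || cfg[[f]] < 0 ||
        cfg[[f]] != round(cfg[[f]]))
      stop_config("invalid config field '%s': must be a non-negative count", f)
  if (cfg$n_genes < 1) stop_config("invalid config field 'n_genes': must be >= 1")
  if (length(samples_per_group) == 1)
    cfg$samples_per_group <- rep(samples_per_group, 2)
  if (length(cfg$samples_per_group) != 2 || any(cfg$samples_per_group < 2) ||
      cfg$samples_per_group[1] > cfg$samples_per_group[2])
    stop_config("invalid config field 'samples_per_group': need an increasing range >= 2")
  for (f in c("winner_penetrance", "shared_block_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_config("invalid config field '%s': must lie in [0, 1]", f)
  if (!(between_block_r >= 0 && between_block_r < within_block_r &&
        within_block_r <= 1))
    stop_config("invalid config fields: need 0 <= between_block_r < within_block_r <= 1")
  if (within_block_r == 1)
    stop_config("invalid config field 'within_block_r': 1 is unreachable under noise")
  if (n_blocks * block_size > n_genes)
    stop_config("invalid config: n_blocks * block_size exceeds n_genes")
  if (cfg$n_winner_up + cfg$n_winner_down > n_genes)
    stop_config("invalid config: planted winners exceed n_genes")
  for (f in c("additive_sd", "multiplicative_sd", "intensity_floor", "true_hr"))
    if (cfg[[f]] <= 0) stop_config("invalid config field '%s': must be positive", f)
  if (effect_size < 0) stop_config("invalid config field 'effect_size': must be >= 0")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

gene_labels <- function(n) sprintf("g%05d", seq_len(n))

## globally fixed winner directions: first n_up genes up, next n_down down
planted_directions <- function(config) {
  g <- gene_labels(config$n_genes)
  up <- g[seq_len(config$n_winner_up)]
  down <- g[config$n_winner_up + seq_len(config$n_winner_down)]
  list(up = up, down = down)
}

#' Generate one synthetic expression study
#'
#' Raw intensities follow `y = background + mu_i * exp(eta) + eps` with a
#' log-normal per-gene baseline `mu_i`, multiplicative log-normal noise
#' and additive Gaussian noise. Planted winner genes receive a
#' `2^(+-effect_size)` multiplicative shift of `mu_i` in the case group
#' (a mean shift of about `effect_size` on the glog2 scale), each with
#' probability `winner_penetrance`. Intensities are clipped at
#' `intensity_floor`. Generation is a pure function of `(config,
#' study_seed)`.
#'
#' @param config a [sim_config()].
#' @param disease_class `"LC"` or `"LD"`.
#' @param study_seed integer seed for this study.
#' @param study_id study label.
#' @return a list with elements `study` (an `ExpressionStudy`, scale raw)
#'   and `truth` (planted gene sets for this study).
#' @export
gen_expression_study <- function(config, disease_class = "LC",
                                 study_seed = config$seed,
                                 study_id = "S1") {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  dirs <- planted_directions(config)
  with_seed(study_seed, {
    m <- config$n_genes
    n_per <- if (config$samples_per_group[1] == config$samples_per_group[2])
      config$samples_per_group[1]
    else sample(seq(config$samples_per_group[1], config$samples_per_group[2]), 1)
    n <- 2L * n_per
    genes <- gene_labels(m)
    mu <- rlnorm(m, meanlog = config$baseline_meanlog, sdlog = config$baseline_sdlog)
    group <- rep(c("control", "case"), each = n_per)
    ## penetrance: which planted genes fire in THIS study
    fire_up <- dirs$up[runif(length(dirs$up)) <= config$winner_penetrance]
    fire_down <- dirs$down[runif(length(dirs$down)) <= config$winner_penetrance]
    shift <- rep(0, m)
    names(shift) <- genes
    shift[fire_up] <- config$effect_size
    shift[fire_down] <- -config$effect_size
    mu_mat <- matrix(mu, m, n)
    case_cols <- which(group == "case")
    mu_mat[, case_cols] <- mu_mat[, case_cols] * 2^shift
    eta <- matrix(rnorm(m * n, sd = config$multiplicative_sd), m, n)
    eps <- matrix(rnorm(m * n, sd = config$additive_sd), m, n)
    y <- config$background + mu_mat * exp(eta) + eps
    y <- pmax(y, config$intensity_floor)
    dimnames(y) <- list(genes, sprintf("%s_%s%02d", study_id,
                                       ifelse(group == "case", "T", "N"),
                                       c(seq_len(n_per), seq_len(n_per))))
    study <- expression_study(study_id, disease_class, y, group, scale = "raw")
    truth <- list(planted_up = fire_up, planted_down = fire_down,
                  global_up = dirs$up, global_down = dirs$down)
    list(study = study, truth = truth)
  })
}

#' Generate a full multi-study collection
#'
#' Produces `n_lc_studies` LC studies followed by `n_ld_studies` LD
#' studies. The same designated winner set (with globally fixed
#' directions) is planted in every study where the per-study penetrance
#' draw fires, so consensus recovery downstream is testable against
#' truth.
#'
#' @param config a [sim_config()].
#' @return a list with one element per study, each a list
#'   `(study, truth)` as returned by [gen_expression_study()].
#' @export
gen_study_collection <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n_lc <- config$n_lc_studies
  n_ld <- config$n_ld_studies
  lapply(seq_len(n_lc + n_ld), function(i) {
    cls <- if (i <= n_lc) "LC" else "LD"
    id <- if (i <= n_lc) sprintf("LC%d", i) else sprintf("LD%d", i - n_lc)
    gen_expression_study(config, cls, child_seed(config$seed, i), id)
  })
}

## latent-factor block sample: rows genes, columns samples, unit variance
block_factor_matrix <- function(membership, n_samples, rw, rb) {
  m <- length(membership)
  blocks <- setdiff(unique(membership), NA)
  g <- rnorm(n_samples)                       # global factor (between-block r)
  x <- matrix(rnorm(m * n_samples) * sqrt(1 - rw), m, n_samples)
  for (b in blocks) {
    idx <- which(membership == b)
    f <- rnorm(n_samples)
    sgn <- rep(1, length(idx))
    x[idx, ] <- x[idx, ] +
      sgn * (sqrt(rb) * matrix(g, length(idx), n_samples, byrow = TRUE) +
             sqrt(rw - rb) * matrix(f, length(idx), n_samples, byrow = TRUE))
  }
  free <- which(is.na(membership))
  if (length(free))
    x[free, ] <- matrix(rnorm(length(free) * n_samples), length(free), n_samples)
  x
}

#' Generate a coexpression-structured pair of studies
#'
#' Two studies on the glog2 scale whose genes follow a latent-factor
#' block model: gene `i` in block `b` is
#' `x = sqrt(rb) * g + sqrt(rw - rb) * f_b + sqrt(1 - rw) * e`, giving
#' correlation `rw` within and `rb` between blocks. Shared blocks keep
#' the same membership in both studies; the genes of non-shared blocks
#' are re-assigned to scrambled blocks in the second study.
#'
#' @param config a [sim_config()].
#' @return list with `study_a`, `study_b` (both `ExpressionStudy`,
#'   scale glog2) and `truth` holding `block_membership` per study,
#'   `shared_blocks`, and `shared_edges` (the planted within-block edge
#'   keys of shared blocks).
#' @export
gen_coexpression_pair <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_seed(child_seed(config$seed, 101L), {
    m <- config$n_genes
    genes <- gene_labels(m)
    n_per <- config$samples_per_group[2]
    n <- 2L * n_per
    membership <- rep(NA_character_, m)
    for (b in seq_len(config$n_blocks))
      membership[(b - 1) * config$block_size + seq_len(config$block_size)] <-
        sprintf("B%02d", b)
    n_shared <- round(config$shared_block_fraction * config$n_blocks)
    shared <- sprintf("B%02d", seq_len(n_shared))
    memb_b <- membership
    nonshared_idx <- which(!is.na(membership) & !membership %in% shared)
    if (length(nonshared_idx) > 1)
      memb_b[nonshared_idx] <- sample(membership[nonshared_idx])
    mu <- rnorm(m, mean = 8, sd = 1.5)
    mk <- function(memb, id) {
      x <- mu + block_factor_matrix(memb, n, config$within_block_r,
                                    config$between_block_r)
      dimnames(x) <- list(genes, sprintf("%s_S%03d", id, seq_len(n)))
      expression_study(id, "LC", x, rep(c("control", "case"), each = n_per),
                       scale = "glog2")
    }
    study_a <- mk(membership, "NETA")
    ## different factors for B: regenerating uses fresh RNG draws, but the
    ## SHARED blocks must share no factors with A -- sharing is structural
    ## (same membership), the realized factors are independent per study.
    study_b <- mk(memb_b, "NETB")
    shared_edges <- unlist(lapply(shared, function(b) {
      g <- genes[which(membership == b)]
      if (length(g) < 2) return(character(0))
      pr <- combn(sort(g), 2)
      edge_keys(pr[1, ], pr[2, ])
    }))
    list(study_a = study_a, study_b = study_b,
         truth = list(block_membership_a = setNames(membership, genes),
                      block_membership_b = setNames(memb_b, genes),
                      shared_blocks = shared, shared_edges = shared_edges))
  })
}

#' Generate a synthetic survival cohort
#'
#' Expression is drawn standard normal and split at the median into
#' `high`/`low` groups; event times are exponential with baseline hazard
#' for the low group and hazard `true_hr` times larger for the high
#' group. Censoring is independent Uniform(0, u) with `u` calibrated
#' numerically so the marginal censoring probability equals
#' `censor_rate`. Categorical noise covariates (stage, gender, smoking)
#' are attached.
#'
#' @param n number of subjects (>= 2).
#' @param true_hr planted hazard ratio (> 0).
#' @param censor_rate marginal censoring probability in `[0, 1)`.
#' @param seed integer seed.
#' @param baseline_hazard event rate of the low-expression group.
#' @return a `data.frame` of class `SurvivalCohort` with columns
#'   `subject`, `time`, `event`, `group`, `expression`, `stage`,
#'   `gender`, `smoking`.
#' @export
gen_survival_cohort <- function(n, true_hr = 2, censor_rate = 0.2,
                                seed = 1L, baseline_hazard = 0.1) {
  if (n < 2) stop_config("invalid config field 'n': need n >= 2")
  if (true_hr <= 0) stop_config("invalid config field 'true_hr': must be positive")
  if (censor_rate < 0 || censor_rate >= 1)
    stop_config("invalid config field 'censor_rate': must lie in [0, 1)")
  with_seed(seed, {
    expr <- rnorm(n)
    grp <- ifelse(expr > median(expr), "high", "low")
    rate <- ifelse(grp == "high", baseline_hazard * true_hr, baseline_hazard)
    t_event <- rexp(n, rate = rate)
    if (censor_rate > 0) {
      ## P(C < T) for T ~ Exp(lambda), C ~ U(0, u) is (1 - exp(-lambda u))/(lambda u)
      pc <- function(u) mean((1 - exp(-rate * u)) / (rate * u))
      u <- uniroot(function(u) pc(u) - censor_rate, lower = 1e-6, upper = 1e6,
                   tol = 1e-9)$root
      cens <- runif(n, 0, u)
      time <- pmin(t_event, cens)
      event <- as.integer(t_event <= cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    out <- data.frame(
      subject = sprintf("P%05d", seq_len(n)),
      time = pmax(time, 1e-9), event = event, group = grp,
      expression = expr,
      stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE),
      gender = sample(c("female", "male"), n, replace = TRUE),
      smoking = sample(c("never", "ever"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    class(out) <- c("SurvivalCohort", "data.frame")
    out
  })
}
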