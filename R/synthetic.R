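# Dirichlet sampler: one row per draw, proportional gamma construction.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# Normal truncated below at `floor` by rejection sampling; sd = 0 is the
# degenerate point mass at the mean.
rnorm_floor <- function(n, mean, sd, floor) {
  if (sd < 0) stop("negative SD in clinical model", call. = FALSE)
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= floor
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Default genus panel for synthetic cohorts
#'
#' The smallest panel covering every genus in the SBP-MI and HBCDI
#' formulas plus the genera implicated in longitudinal improvement or
#' progression (Enterococcus, Haemophilus, Akkermansia, Bifidobacterium),
#' and a `Remainder` pseudo-genus absorbing residual community mass.
#'
#' @return character vector of genus names.
#' @export
default_genus_panel <- function() {
  c("Streptococcus", "Escherichia-Shigella", "Klebsiella", "Veillonella",
    "Prevotella", "Roseburia", "Faecalibacterium", "Bacteroides",
    "Lactobacillus", "Ruminococcus",
    "Enterococcus", "Haemophilus", "Akkermansia", "Bifidobacterium",
    "Remainder")
}

# Per-group Dirichlet concentrations over the default panel.  Means
# (alpha / total) follow the staged directionality of the disease axis:
# pathobionts (rows 1-4) rise HC -> CC -> NSBP -> SBP, SCFA producers
# (rows 5-8) fall.  Totals are fixed at 20 per group, giving
# between-subject variability typical of genus-level gut profiles.
default_dirichlet_params <- function() {
  panel <- default_genus_panel()
  a <- cbind(
    HC   = c(0.5, 0.5, 0.3, 0.3, 8.0, 4.0, 6.0, 12.0, 0.8, 2.0,
             0.3, 0.3, 0.6, 1.2, 13.2),
    CC   = c(1.0, 1.2, 0.8, 0.6, 6.0, 2.5, 5.0, 9.0, 0.8, 1.6,
             0.5, 0.5, 0.6, 1.0, 18.9),
    NSBP = c(2.5, 3.0, 2.0, 1.2, 3.0, 1.5, 3.0, 5.0, 1.0, 1.0,
             1.5, 1.2, 0.8, 0.8, 22.5),
    SBP  = c(4.0, 6.0, 4.5, 2.5, 1.5, 0.8, 1.0, 3.0, 1.2, 0.6,
             1.5, 1.2, 1.2, 0.6, 20.4))
  rownames(a) <- panel
  t(a) * 0.4  # groups x genera, total concentration 20 per group
}

default_clinical_model <- function() {
  list(
    HC   = list(inr = c(1.0, 0.07), meld = c(7.0, 0.8),  history = 0),
    CC   = list(inr = c(1.1, 0.12), meld = c(8.5, 1.5),  history = 0),
    NSBP = list(inr = c(1.4, 0.30), meld = c(12.5, 3.0), history = 0),
    SBP  = list(inr = c(1.7, 0.40), meld = c(18.5, 3.5), history = 0.2))
}

#' Configure a synthetic microbiome cohort
#'
#' Bundles everything the generator needs: group sizes, the genus panel,
#' per-group Dirichlet concentration vectors, per-group clinical normals
#' (INR and MELD, truncated at physiologic floors 0.8 and 6) and
#' previous-SBP-history prevalence, the outcome equation, and the paired
#' follow-up design (number of pairs, arm sizes, per-genus multiplicative
#' drift at follow-up per arm).
#'
#' One root seed governs everything; each generation stage draws from its
#' own deterministically derived child stream, so regenerating one stage
#' never perturbs another.
#'
#' @param group_sizes named integer vector of samples per group.
#' @param genus_panel ordered unique genus names.
#' @param dirichlet_params groups x genera matrix of positive
#'   concentrations (rownames = groups, colnames = panel).
#' @param clinical_model named list per group:
#'   `list(inr = c(mean, sd), meld = c(mean, sd), history = prevalence)`.
#' @param outcome_coefficients a [risk_equation()]; defaults to the
#'   published SBP-RP equation.
#' @param n_pairs number of paired baseline/follow-up subjects.
#' @param arm_sizes named vector splitting `n_pairs` into arms.
#' @param drift named list per arm of named positive per-genus
#'   multiplicative abundance shifts applied at follow-up.
#' @param paired_group group whose concentrations seed the paired baselines.
#' @param seed integer root seed.
#' @return an object of class `cohort_config`.
#' @seealso [default_cohort_config()], [prospective_cohort_config()]
#' @export
cohort_config <- function(group_sizes,
                          genus_panel = default_genus_panel(),
                          dirichlet_params = NULL,
                          clinical_model = NULL,
                          outcome_coefficients = sbp_rp_equation(),
                          n_pairs = 0,
                          arm_sizes = c(improved = 0, progression = 0),
                          drift = default_drift(),
                          paired_group = NULL,
                          seed = 2025) {
  if (anyDuplicated(genus_panel)) stop("genus panel has duplicate names",
                                       call. = FALSE)
  if (any(group_sizes < 0)) stop("group sizes must be >= 0", call. = FALSE)
  if (is.null(names(group_sizes))) stop("group_sizes must be named",
                                        call. = FALSE)
  if (is.null(dirichlet_params)) {
    dirichlet_params <- default_dirichlet_params()
  }
  if (!all(names(group_sizes) %in% rownames(dirichlet_params))) {
    stop("dirichlet_params missing group(s): ",
         paste(setdiff(names(group_sizes), rownames(dirichlet_params)),
               collapse = ", "), call. = FALSE)
  }
  if (!identical(colnames(dirichlet_params), genus_panel)) {
    stop("dirichlet_params columns must match the genus panel", call. = FALSE)
  }
  bad <- which(dirichlet_params <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive Dirichlet concentration for genus '%s' in group '%s'",
                 colnames(dirichlet_params)[bad[1, 2]],
                 rownames(dirichlet_params)[bad[1, 1]]), call. = FALSE)
  }
  if (is.null(clinical_model)) clinical_model <- default_clinical_model()
  for (arm in names(drift)) {
    if (any(drift[[arm]] <= 0)) {
      stop("drift factors must be positive (arm '", arm, "')", call. = FALSE)
    }
  }
  if (n_pairs > 0 && sum(arm_sizes) != n_pairs) {
    stop("arm_sizes must sum to n_pairs", call. = FALSE)
  }
  if (is.null(paired_group)) {
    paired_group <- if ("NSBP" %in% rownames(dirichlet_params)) "NSBP"
                    else rownames(dirichlet_params)[1]
  }
  structure(list(group_sizes = group_sizes, genus_panel = genus_panel,
                 dirichlet_params = dirichlet_params,
                 clinical_model = clinical_model,
                 outcome_coefficients = outcome_coefficients,
                 n_pairs = n_pairs, arm_sizes = arm_sizes, drift = drift,
                 paired_group = paired_group, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default per-genus follow-up drift per arm
#'
#' Improved follow-ups shrink the pathobionts (Klebsiella, Streptococcus,
#' Enterococcus and companions) and expand the SCFA producers; progression
#' follow-ups expand Klebsiella and Haemophilus while beneficial
#' commensals (Akkermansia, Bifidobacterium, Lactobacillus) recede.
#'
#' @return named list of named numeric drift vectors.
#' @export
default_drift <- function() {
  list(
    improved = c("Klebsiella" = 0.5, "Streptococcus" = 0.6,
                 "Enterococcus" = 0.6, "Escherichia-Shigella" = 0.7,
                 "Veillonella" = 0.8, "Bacteroides" = 1.4,
                 "Prevotella" = 1.4, "Faecalibacterium" = 1.3),
    progression = c("Klebsiella" = 1.8, "Haemophilus" = 2.2,
                    "Escherichia-Shigella" = 1.3, "Akkermansia" = 0.7,
                    "Bifidobacterium" = 0.7, "Lactobacillus" = 0.7))
}

#' Ready-made cohort configurations
#'
#' `default_cohort_config()` emulates the staged case-control design
#' (HC n=40, CC n=30, NSBP n=40, SBP n=25) with the paired follow-up
#' sub-study (40 pairs split 32 improved / 8 progression).
#' `prospective_cohort_config()` emulates a single prospective arm of
#' ascitic cirrhosis patients followed for incident SBP.
#'
#' @param seed integer root seed; default 2025.
#' @param n prospective cohort size; default 140.
#' @return a [cohort_config()].
#' @export
default_cohort_config <- function(seed = 2025) {
  cohort_config(group_sizes = c(HC = 40, CC = 30, NSBP = 40, SBP = 25),
                n_pairs = 40, arm_sizes = c(improved = 32, progression = 8),
                seed = seed)
}

#' @rdname default_cohort_config
#' @export
prospective_cohort_config <- function(n = 140, seed = 2025) {
  dp <- default_dirichlet_params()
  dp <- rbind(dp, ASC = dp["NSBP", ])
  cm <- default_clinical_model()
  cm$ASC <- list(inr = c(1.5, 0.35), meld = c(13, 4), history = 0.15)
  cohort_config(group_sizes = c(ASC = n), dirichlet_params = dp,
                clinical_model = cm, paired_group = "ASC", seed = seed)
}

#' Draw staged community compositions
#'
#' One Dirichlet draw per sample from its group's concentration vector;
#' every row sums to 1 exactly (up to floating point).  Sample identifiers
#' are `<group>_<k>`.
#'
#' @param config a [cohort_config()].
#' @return an [abundance_table()] with attribute `"groups"` (per-sample
#'   group labels).
#' @export
generate_compositions <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(child_seed(config$seed, "compositions"))
  blocks <- list(); groups <- character(); ids <- character()
  for (g in names(config$group_sizes)) {
    ng <- config$group_sizes[[g]]
    if (ng == 0) next
    blocks[[g]] <- rdirichlet(ng, config$dirichlet_params[g, ])
    ids <- c(ids, sprintf("%s_%03d", g, seq_len(ng)))
    groups <- c(groups, rep(g, ng))
  }
  vals <- do.call(rbind, blocks)
  out <- abundance_table(vals, sample_ids = ids,
                         genus_names = config$genus_panel)
  attr(out, "groups") <- groups
  out
}

#' Attach clinical covariates to generated compositions
#'
#' INR and MELD are drawn from the per-group normals truncated at the
#' physiologic floors (INR >= 0.8, MELD >= 6) by rejection sampling;
#' previous-SBP history is Bernoulli with the per-group prevalence.
#'
#' @param config a [cohort_config()].
#' @param abundance the matching [generate_compositions()] output.
#' @return a `synthetic_cohort`: list with `abundance`, `metadata` (data
#'   frame: sample_id, subject_id, timepoint, group, inr, meld, history,
#'   sbp_mi, hbcdi) and `config`.
#' @export
generate_clinical <- function(config, abundance) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- attr(abundance, "groups")
  if (is.null(groups)) {
    groups <- sub("_[0-9]+$", "", rownames(abundance))
  }
  stopifnot(length(groups) == nrow(abundance))
  set.seed(child_seed(config$seed, "clinical"))
  n <- nrow(abundance)
  inr <- numeric(n); meld <- numeric(n); history <- integer(n)
  for (g in unique(groups)) {
    cm <- config$clinical_model[[g]]
    if (is.null(cm)) stop("no clinical model for group '", g, "'",
                          call. = FALSE)
    idx <- which(groups == g)
    inr[idx] <- rnorm_floor(length(idx), cm$inr[1], cm$inr[2], floor = 0.8)
    meld[idx] <- rnorm_floor(length(idx), cm$meld[1], cm$meld[2], floor = 6)
    history[idx] <- stats::rbinom(length(idx), 1, cm$history)
  }
  md <- data.frame(sample_id = rownames(abundance),
                   subject_id = rownames(abundance),
                   timepoint = "baseline", group = groups,
                   inr = inr, meld = meld, history = history,
                   stringsAsFactors = FALSE)
  md$sbp_mi <- compute_index(abundance, sbpmi_definition())$score
  md$hbcdi <- compute_index(abundance, hbcdi_definition())$score
  structure(list(abundance = abundance, metadata = md, config = config),
            class = "synthetic_cohort")
}

#' Simulate incident-SBP outcomes from a risk equation
#'
#' Draws `outcome ~ Bernoulli(expit(linear predictor))` per sample using
#' the supplied coefficients (default: the published SBP-RP equation on
#' SBP-MI, INR and previous history).  The per-sample true probability is
#' retained in `metadata$true_prob` for calibration checks.
#'
#' @param cohort a `synthetic_cohort` (see [generate_clinical()]).
#' @param equation a [risk_equation()].
#' @return the cohort with `outcome` and `true_prob` metadata columns.
#' @export
simulate_outcomes <- function(cohort, equation = sbp_rp_equation()) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(equation, "risk_equation"))
  md <- cohort$metadata
  need <- names(equation$coefficients)
  for (v in need) {
    if (!v %in% names(md)) {
      stop("metadata lacks covariate '", v, "'", call. = FALSE)
    }
    bad <- which(!is.finite(md[[v]]))
    if (length(bad)) {
      stop(sprintf("missing covariate '%s' for sample '%s'", v,
                   md$sample_id[bad[1]]), call. = FALSE)
    }
  }
  lp <- linear_predictor(equation, md)
  prob <- stats::plogis(lp)
  set.seed(child_seed(cohort$config$seed, "outcomes"))
  md$true_prob <- prob
  md$outcome <- stats::rbinom(nrow(md), 1, prob)
  cohort$metadata <- md
  cohort
}

#' Generate a paired baseline/follow-up cohort
#'
#' Baseline compositions are Dirichlet draws from the paired group's
#' concentrations; each subject's follow-up composition is the renormalized
#' product of its baseline abundances with the arm-specific per-genus drift
#' factors, so within-subject change is driven entirely by the configured
#' drift direction.  Arm sizes are emitted exactly as configured.
#'
#' @param config a [cohort_config()] with `n_pairs > 0`.
#' @return a `synthetic_cohort` whose metadata has two rows per subject
#'   (timepoints `baseline` and `followup`) and an `arm` column.
#' @export
generate_paired_followup <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_pairs <= 0) stop("n_pairs must be > 0", call. = FALSE)
  for (arm in names(config$drift)) {
    if (any(config$drift[[arm]] <= 0)) {
      stop("drift factors must be positive (arm '", arm, "')", call. = FALSE)
    }
  }
  set.seed(child_seed(config$seed, "pairs"))
  n <- config$n_pairs
  base <- rdirichlet(n, config$dirichlet_params[config$paired_group, ])
  colnames(base) <- config$genus_panel
  arms <- rep(names(config$arm_sizes), times = config$arm_sizes)

  follow <- base
  for (arm in names(config$drift)) {
    idx <- which(arms == arm)
    if (!length(idx)) next
    mult <- rep(1, length(config$genus_panel))
    names(mult) <- config$genus_panel
    d <- config$drift[[arm]]
    unknown <- setdiff(names(d), config$genus_panel)
    if (length(unknown)) {
      stop("drift names genus not in panel: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    mult[names(d)] <- d
    shifted <- sweep(base[idx, , drop = FALSE], 2, mult, `*`)
    follow[idx, ] <- shifted / rowSums(shifted)
  }

  subj <- sprintf("P%03d", seq_len(n))
  vals <- rbind(base, follow)
  ids <- c(paste0(subj, "_baseline"), paste0(subj, "_followup"))
  ab <- abundance_table(vals, sample_ids = ids,
                        genus_names = config$genus_panel)
  md <- data.frame(
    sample_id = ids, subject_id = rep(subj, 2),
    timepoint = rep(c("baseline", "followup"), each = n),
    group = config$paired_group, arm = rep(arms, 2),
    stringsAsFactors = FALSE)
  attr(ab, "groups") <- md$group
  structure(list(abundance = ab, metadata = md, config = config),
            class = "synthetic_cohort")
}

#' Generate a complete cohort in one call
#'
#' Compositions, clinical covariates, index scores and simulated outcomes,
#' in that order, each from its own child seed stream.
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort` with outcomes.
#' @export
simulate_cohort <- function(config) {
  ab <- generate_compositions(config)
  cohort <- generate_clinical(config, ab)
  simulate_outcomes(cohort, config$outcome_coefficients)
}

#' Simulate a covariate cohort directly from a risk equation
#'
#' Draws the model covariates from their stated marginal distributions
#' (SBP-MI normal, INR normal truncated at the physiologic floor 0.8,
#' previous history Bernoulli) and outcomes from the logistic model defined
#' by `equation`, bypassing the compositional generator.  This is the
#' canonical parameter-recovery benchmark: fitting the same model back to
#' the simulated data must reproduce the equation's coefficients up to
#' sampling error.  Covariates and outcomes use separate child streams of
#' the root seed.
#'
#' @param n number of subjects; default 20000.
#' @param seed root seed; default 2025.
#' @param equation a [risk_equation()]; default [sbp_rp_equation()].
#' @param sbp_mi,inr `c(mean, sd)` of the covariate distributions.
#' @param history_prevalence Bernoulli prevalence of previous SBP history.
#' @return data frame with columns `sbp_mi`, `inr`, `history`,
#'   `true_prob`, `outcome`.
#' @export
simulate_equation_cohort <- function(n = 20000, seed = 2025,
                                     equation = sbp_rp_equation(),
                                     sbp_mi = c(-0.5, 1),
                                     inr = c(1.6, 0.4),
                                     history_prevalence = 0.15) {
  set.seed(child_seed(seed, "clinical"))
  d <- data.frame(
    sbp_mi = stats::rnorm(n, sbp_mi[1], sbp_mi[2]),
    inr = rnorm_floor(n, inr[1], inr[2], floor = 0.8),
    history = stats::rbinom(n, 1, history_prevalence))
  d$true_prob <- risk_probability(equation, d)
  set.seed(child_seed(seed, "outcomes"))
  d$outcome <- stats::rbinom(n, 1, d$true_prob)
  d
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d genera (seed %d)\n",
              nrow(x$abundance), ncol(x$abundance), x$config$seed))
  print(table(x$metadata$group))
  if ("outcome" %in% names(x$metadata)) {
    cat(sprintf("events: %d / %d\n", sum(x$metadata$outcome),
                nrow(x$metadata)))
  }
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Abundance as TSV (first column sample id), metadata as CSV, and the
#' configuration echo (group sizes, concentrations, clinical model,
#' equation, seed) as JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_abundance(cohort$abundance, file.path(dir, "abundance.tsv"))
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  jsonlite::write_json(
    list(group_sizes = as.list(cfg$group_sizes),
         genus_panel = cfg$genus_panel,
         dirichlet_params = as.data.frame(cfg$dirichlet_params),
         clinical_model = cfg$clinical_model,
         outcome_coefficients = list(
           intercept = cfg$outcome_coefficients$intercept,
           coefficients = as.list(cfg$outcome_coefficients$coefficients)),
         n_pairs = cfg$n_pairs, arm_sizes = as.list(cfg$arm_sizes),
         drift = lapply(cfg$drift, as.list),
         paired_group = cfg$paired_group, seed = cfg$seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}
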