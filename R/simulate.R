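#' Configuration for the synthetic exposure-experiment generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' 16 engineered-nanomaterial exposure groups (4 materials x 4 surface
#' chemistries) plus one matched control group per dispersant, 3
#' biological replicates each; two probe biotypes with lncRNA intensities
#' systematically lower than mRNA; negative-control probes defining
#' per-sample background; additive, mean-zero batch effects on two batch
#' variables (labeling, array); planted per-exposure differential-expression
#' effects whose magnitude scales with a per-group severity; and planted
#' lncRNA-regulated mRNA modules whose members share a per-group effect
#' vector, so their cross-contrast log2FC profiles correlate at +/-1
#' before noise.
#'
#' @param n_lnc,n_mrna,n_negctrl probe counts per biotype.
#' @param groups tibble of exposure groups (`material`, `surface`,
#'   `dispersant`, `severity`); defaults to the 16-exposure + 2-control
#'   design with severities 1 (high), 0.5 (medium), 0 (low) that multiply
#'   `effect_size_log2`.
#' @param reps_per_group biological replicates per group.
#' @param baseline_log2 mean log2 intensity of mRNA probes.
#' @param baseline_sd probe-to-probe SD of baseline log2 intensity.
#' @param lnc_mean_offset additive log2 offset of lncRNA baselines
#'   (negative: lncRNAs are dimmer than mRNAs).
#' @param bg_mean_log2,bg_sd_log2 log2-normal background distribution of
#'   negative-control probes; the defaults place mean + 2 SD near the 10th
#'   percentile of true-probe baselines so the background filter removes
#'   roughly 10 percent of probes.
#' @param batch_sd SD of the additive per-probe batch shifts (log2 units).
#' @param noise_sd SD of the i.i.d. Gaussian measurement noise (log2 units).
#' @param n_modules number of planted lncRNA-mRNA co-regulation modules.
#' @param module_n_lnc,module_n_mrna members per module (disjoint across
#'   modules).
#' @param effect_size_log2 planted effect magnitude at severity 1.
#' @param frac_de fraction of probes made independently
#'   exposure-responsive: each such probe receives its own dense random
#'   effect vector (per-group `N(0, 1)` weights scaled by
#'   `severity * effect_size_log2`), so responsive probes are mutually
#'   uncorrelated and planted modules remain the only truly correlated
#'   pairs. The fraction of these probes differentially expressed in a
#'   given group follows from its severity.
#' @param seed integer; one global seed drives named RNG sub-streams.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lnc = 2000L, n_mrna = 8000L, n_negctrl = 200L,
                       groups = default_groups(),
                       reps_per_group = 3L,
                       baseline_log2 = 8.0, baseline_sd = 1.5,
                       lnc_mean_offset = -2.0,
                       bg_mean_log2 = 4.0, bg_sd_log2 = 0.65,
                       batch_sd = 0.5, noise_sd = 0.3,
                       n_modules = 2L, module_n_lnc = 6L, module_n_mrna = 30L,
                       effect_size_log2 = 2.0, frac_de = 0.05,
                       seed = 1L) {
  cfg <- list(n_lnc = as.integer(n_lnc), n_mrna = as.integer(n_mrna),
              n_negctrl = as.integer(n_negctrl), groups = as_tibble(groups),
              reps_per_group = as.integer(reps_per_group),
              baseline_log2 = baseline_log2, baseline_sd = baseline_sd,
              lnc_mean_offset = lnc_mean_offset,
              bg_mean_log2 = bg_mean_log2, bg_sd_log2 = bg_sd_log2,
              batch_sd = batch_sd, noise_sd = noise_sd,
              n_modules = as.integer(n_modules),
              module_n_lnc = as.integer(module_n_lnc),
              module_n_mrna = as.integer(module_n_mrna),
              effect_size_log2 = effect_size_log2, frac_de = frac_de,
              seed = as.integer(seed))
  assert_cols(cfg$groups, c("material", "surface", "dispersant", "severity"), "groups")
  if (any(c(cfg$n_lnc, cfg$n_mrna, cfg$n_negctrl, cfg$reps_per_group) <= 0L)) {
    abort("probe and replicate counts must be positive")
  }
  if (cfg$frac_de < 0 || cfg$frac_de >= 1) abort("frac_de must lie in [0, 1)")
  if (cfg$n_modules * cfg$module_n_lnc > cfg$n_lnc ||
      cfg$n_modules * cfg$module_n_mrna > cfg$n_mrna) {
    abort("module sizes infeasible: modules would exceed available probes")
  }
  structure(cfg, class = "sim_config")
}

#' Default exposure-group design
#'
#' Four materials (CuO, MWCNT, spherical and rod TiO2) in four surface
#' chemistries each, plus one control group per dispersant. MWCNT is
#' dispersed in PBS + BSA, everything else in PBS. Severities encode
#' three planted toxicity magnitudes: CuO Core/COOH/NH2 = 1 (high),
#' all MWCNT and TiO2p NH2/PEG = 0.5 (medium), the rest = 0.
#'
#' @return Tibble with `material`, `surface`, `dispersant`, `severity`.
#' @export
default_groups <- function() {
  g <- tidyr::expand_grid(material = c("CuO", "MWCNT", "TiO2p", "TiO2r"),
                          surface = c("Core", "COOH", "NH2", "PEG")) |>
    mutate(dispersant = ifelse(.data$material == "MWCNT", "PBS_BSA", "PBS"),
           severity = dplyr::case_when(
             .data$material == "CuO" & .data$surface != "PEG" ~ 1.0,
             .data$material == "MWCNT" ~ 0.5,
             .data$material == "TiO2p" & .data$surface %in% c("NH2", "PEG") ~ 0.5,
             TRUE ~ 0.0))
  dplyr::bind_rows(g,
                   tibble(material = "control", surface = "none",
                          dispersant = c("PBS", "PBS_BSA"), severity = 0))
}

group_label <- function(material, surface, dispersant) {
  ifelse(material == "control", paste0("control_", dispersant),
         paste(material, surface, sep = "-"))
}

#' Simulate a complete expression experiment with ground truth
#'
#' Raw-scale intensities are generated as
#' `2^(baseline + biotype offset + group effect + batch effects + noise)`;
#' negative-control probes are drawn from the background distribution
#' only. Module members receive proportional per-group effect vectors
#' (positive or negative proportionality), so planted lncRNA-mRNA pairs
#' correlate at +/-1 across contrasts before noise. Module 1 is the
#' monotone toxicity-response module: its per-group weight equals the
#' group severity and its lncRNA members are up-regulated, emulating the
#' panel of lncRNAs tied to the DNA-damage mRNA cluster; further modules
#' receive independent per-group weights so modules are mutually
#' near-uncorrelated. Identical seed implies identical output.
#'
#' @param cfg a [sim_config()].
#' @return List with `expr` (raw-scale [expr_matrix]), `design` (tibble),
#'   `annotation` (tibble), and `truth`: a list of `de_probes`
#'   (group, probe_id, true_log2fc), `true_edges` (lnc_id, mrna_id),
#'   `modules` (probe_id, module_id, coef) and `group_severity`.
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  ann <- sim_annotation(cfg)
  design <- sim_design(cfg)
  grp <- cfg$groups |>
    mutate(group = group_label(.data$material, .data$surface, .data$dispersant))
  n_groups <- nrow(grp)
  n_true <- cfg$n_lnc + cfg$n_mrna
  true_ids <- ann$probe_id[ann$biotype != "negative_control"]
  lnc_ids <- ann$probe_id[ann$biotype == "lncRNA"]
  mrna_ids <- ann$probe_id[ann$biotype == "mRNA"]

  # planted module structure: disjoint memberships, proportional effects
  modules <- with_stream(cfg$seed, "modules", {
    if (cfg$n_modules == 0L) {
      tibble(probe_id = character(), module_id = integer(), coef = numeric())
    } else {
      m_lnc <- matrix(sample(lnc_ids, cfg$n_modules * cfg$module_n_lnc), ncol = cfg$n_modules)
      m_mrna <- matrix(sample(mrna_ids, cfg$n_modules * cfg$module_n_mrna), ncol = cfg$n_modules)
      purrr::map_dfr(seq_len(cfg$n_modules), function(m) {
        # module-level proportionality sign: odd modules positively, even
        # modules negatively co-regulated with their lncRNA drivers, so
        # correlation-matrix clusters are sign-coherent ("opposingly
        # correlated" cluster pairs)
        s_m <- if (m %% 2L == 1L) 1 else -1
        tibble(probe_id = c(m_lnc[, m], m_mrna[, m]), module_id = m,
               coef = c(rep(1, cfg$module_n_lnc), rep(s_m, cfg$module_n_mrna)))
      })
    }
  })
  module_weights <- with_stream(cfg$seed, "module-weights", {
    w <- matrix(0, nrow = max(cfg$n_modules, 1L), ncol = n_groups)
    if (cfg$n_modules >= 1L) w[1L, ] <- grp$severity
    if (cfg$n_modules >= 2L) {
      # independent Gaussian weights: co-regulation patterns are
      # module-specific and mutually near-uncorrelated
      for (m in 2:cfg$n_modules) w[m, ] <- grp$severity * rnorm(n_groups)
    }
    colnames(w) <- grp$group
    w
  })

  # per-group effect matrix over true probes
  effects <- matrix(0, nrow = n_true, ncol = n_groups,
                    dimnames = list(true_ids, grp$group))
  if (nrow(modules) > 0L) {
    idx <- match(modules$probe_id, true_ids)
    for (i in seq_len(nrow(modules))) {
      effects[idx[i], ] <- modules$coef[i] * cfg$effect_size_log2 *
        module_weights[modules$module_id[i], ]
    }
  }
  # independent exposure-responsive probes: dense severity-scaled random
  # effect vectors, so that no two of them share a proportional profile
  # (planted modules remain the only truly correlated pairs)
  effects <- effects + with_stream(cfg$seed, "probe-effects", {
    extra <- matrix(0, nrow = n_true, ncol = n_groups)
    free <- setdiff(true_ids, modules$probe_id)
    n_resp <- min(round(cfg$frac_de * n_true), length(free))
    if (n_resp > 0L && any(grp$severity > 0)) {
      resp <- sample(free, n_resp)
      z <- matrix(rnorm(n_resp * n_groups), nrow = n_resp)
      extra[match(resp, true_ids), ] <-
        sweep(z, 2L, grp$severity * cfg$effect_size_log2, `*`)
    }
    extra
  })

  baseline <- with_stream(cfg$seed, "baseline", {
    b <- rnorm(n_true, cfg$baseline_log2, cfg$baseline_sd)
    b[true_ids %in% lnc_ids] <- b[true_ids %in% lnc_ids] + cfg$lnc_mean_offset
    # effect-carrying probes are expressed by construction: a planted
    # differential effect in a probe below detection background would be
    # unobservable on any platform, so their baselines are floored just
    # above the expected background threshold
    carries_effect <- rowSums(effects != 0) > 0
    floor_log2 <- cfg$bg_mean_log2 + 2 * cfg$bg_sd_log2 + 1
    b[carries_effect] <- pmax(b[carries_effect], floor_log2)
    b
  })

  n_samples <- nrow(design)
  gcol <- match(design$group, grp$group)
  batch <- with_stream(cfg$seed, "batch", {
    shift_for <- function(levels_vec) {
      lv <- sort(unique(levels_vec))
      g <- matrix(rnorm(n_true * length(lv), 0, cfg$batch_sd), nrow = n_true)
      g <- g - rowMeans(g)            # mean-zero across batch levels
      g[, match(levels_vec, lv), drop = FALSE]
    }
    shift_for(design$batch_label) + shift_for(design$batch_array)
  })
  noise <- with_stream(cfg$seed, "noise",
                       matrix(rnorm(n_true * n_samples, 0, cfg$noise_sd), nrow = n_true))

  log2_true <- baseline + effects[, gcol, drop = FALSE] + batch + noise
  bg <- with_stream(cfg$seed, "background",
                    matrix(rnorm(cfg$n_negctrl * n_samples, cfg$bg_mean_log2, cfg$bg_sd_log2),
                           nrow = cfg$n_negctrl))
  values <- rbind(log2_true, bg)
  rownames(values) <- c(true_ids, ann$probe_id[ann$biotype == "negative_control"])
  colnames(values) <- design$sample_id
  values <- 2^values[ann$probe_id, , drop = FALSE]

  de_long <- tibble(
    group = rep(grp$group, each = n_true),
    probe_id = rep(true_ids, times = n_groups),
    true_log2fc = as.vector(effects)
  ) |> filter(.data$true_log2fc != 0)

  true_edges <- if (nrow(modules) > 0L) {
    active <- which(apply(abs(module_weights), 1L, max) > 0)
    purrr::map_dfr(active, function(m) {
      mem <- modules[modules$module_id == m, ]
      tidyr::expand_grid(lnc_id = intersect(mem$probe_id, lnc_ids),
                         mrna_id = intersect(mem$probe_id, mrna_ids))
    })
  } else tibble(lnc_id = character(), mrna_id = character())

  list(expr = expr_matrix(values, ann, scale = "raw"),
       design = design,
       annotation = ann,
       truth = list(de_probes = de_long,
                    true_edges = true_edges,
                    modules = modules,
                    module_weights = module_weights,
                    group_severity = grp |> select("group", "severity")),
       config = cfg)
}

#' Simulate a null experiment (all group effects zero)
#'
#' Same generative model as [simulate_experiment()] with every group
#' severity forced to zero: no differential expression, no modules with
#' signal. Used for type-I-error and FDR-control checks.
#'
#' @param cfg a [sim_config()].
#' @return Same structure as [simulate_experiment()]; `truth$de_probes`
#'   and `truth$true_edges` are empty.
#' @export
simulate_null <- function(cfg = sim_config()) {
  cfg$groups$severity <- 0
  simulate_experiment(cfg)
}

sim_annotation <- function(cfg) {
  tibble(
    probe_id = c(sprintf("lnc_%05d", seq_len(cfg$n_lnc)),
                 sprintf("mrna_%05d", seq_len(cfg$n_mrna)),
                 sprintf("negctrl_%04d", seq_len(cfg$n_negctrl))),
    accession = c(sprintf("NR_%06d", seq_len(cfg$n_lnc)),
                  sprintf("NM_%06d", seq_len(cfg$n_mrna)),
                  sprintf("NEG_%04d", seq_len(cfg$n_negctrl))),
    biotype = rep(c("lncRNA", "mRNA", "negative_control"),
                  times = c(cfg$n_lnc, cfg$n_mrna, cfg$n_negctrl))
  )
}

sim_design <- function(cfg) {
  grp <- cfg$groups |>
    mutate(group = group_label(.data$material, .data$surface, .data$dispersant))
  design <- tidyr::expand_grid(grp, replicate = seq_len(cfg$reps_per_group)) |>
    mutate(sample_id = paste0(.data$group, "_r", .data$replicate))
  i <- seq_len(nrow(design))
  design |>
    mutate(batch_label = paste0("L", (i - 1L) %% 2L + 1L),
           batch_array = paste0("A", (i - 1L) %% 3L + 1L)) |>
    select("sample_id", "material", "surface", "dispersant",
           "batch_label", "batch_array", "replicate", "group")
}

#' Build synthetic gene sets around planted modules
#'
#' Creates one gene set per planted module (that module's mRNA members,
#' by accession) plus random filler sets drawn from the mRNA universe,
#' for exercising over-representation analysis with known positives.
#'
#' @param sim result of [simulate_experiment()].
#' @param n_random number of random filler sets.
#' @param random_size size of each filler set.
#' @param seed RNG seed.
#' @return Gene-set tibble compatible with [write_gmt()].
#' @export
simulate_gene_sets <- function(sim, n_random = 40L, random_size = 50L, seed = sim$config$seed) {
  ann <- sim$annotation
  mrna_acc <- ann$accession[ann$biotype == "mRNA"]
  acc_of <- setNames(ann$accession, ann$probe_id)
  mods <- sim$truth$modules
  module_sets <- if (nrow(mods) > 0L) {
    purrr::map_dfr(sort(unique(mods$module_id)), function(m) {
      ids <- mods$probe_id[mods$module_id == m]
      members <- unname(acc_of[ids[startsWith(ids, "mrna_")]])
      tibble(set_id = sprintf("MODULE_%d", m),
             set_name = sprintf("planted co-regulation module %d", m),
             members = list(members))
    })
  } else tibble(set_id = character(), set_name = character(), members = list())
  random_sets <- with_stream(seed, "gene-sets", {
    purrr::map_dfr(seq_len(n_random), function(i) {
      tibble(set_id = sprintf("RANDOM_%03d", i),
             set_name = sprintf("random gene set %d", i),
             members = list(sample(mrna_acc, min(random_size, length(mrna_acc)))))
    })
  })
  dplyr::bind_rows(module_sets, random_sets)
}
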