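#' Immune subset specification
#'
#' A subset is a mixture component of the synthetic cohort: a name, a
#' mixture proportion, a hi/lo phenotyping template realized as means on the
#' arcsinh scale, and per-marker basal (mean, sd) for the functional
#' markers.
#'
#' @param name subset name (e.g. `"memory CD4 Tc"`).
#' @param proportion mixture proportion in (0, 1).
#' @param phenotype named character vector over phenotyping markers with
#'   values `"hi"` or `"lo"`; markers not named default to `"lo"`.
#' @param functional_mean,functional_sd named numeric vectors over
#'   functional markers (arcsinh scale); unnamed defaults fill the rest.
#' @param hi,lo,pheno_sd arcsinh-scale means realizing `"hi"`/`"lo"` and the
#'   phenotyping noise sd.
#' @param fun_mean,fun_sd default basal mean and sd for functional markers.
#' @return An object of class `subset_spec`.
#' @export
subset_spec <- function(name, proportion, phenotype,
                        functional_mean = NULL, functional_sd = NULL,
                        hi = 4.0, lo = 0.5, pheno_sd = 0.4,
                        fun_mean = 1.0, fun_sd = 0.3) {
  stopifnot(proportion > 0, proportion < 1)
  panel <- default_panel()
  pheno_markers <- panel_markers(panel, "phenotyping")
  fun_markers <- panel_markers(panel, "functional")
  if (!all(names(phenotype) %in% pheno_markers))
    stop("unknown phenotyping markers: ",
         paste(setdiff(names(phenotype), pheno_markers), collapse = ", "))
  tmpl <- stats::setNames(rep(lo, length(pheno_markers)), pheno_markers)
  tmpl[names(phenotype)] <- ifelse(phenotype == "hi", hi, lo)
  fm <- stats::setNames(rep(fun_mean, length(fun_markers)), fun_markers)
  fs <- stats::setNames(rep(fun_sd, length(fun_markers)), fun_markers)
  if (!is.null(functional_mean)) fm[names(functional_mean)] <- functional_mean
  if (!is.null(functional_sd)) fs[names(functional_sd)] <- functional_sd
  structure(list(name = name, proportion = proportion,
                 phenotype_mean = tmpl, pheno_sd = pheno_sd,
                 functional_mean = fm, functional_sd = fs),
            class = "subset_spec")
}

#' Default immune subset mixture
#'
#' Eight PBMC subsets with abundances matching a typical healthy mixture:
#' B cells 4.3%, naive CD4 T 25.3%, memory CD4 T 30%, CD8 T 20% (75.3% T
#' cells in total), NK cells 5%, classical monocytes 5.7%, myeloid
#' dendritic cells 8.7% and plasmacytoid dendritic cells 1%.
#'
#' @return list of `subset_spec`.
#' @export
default_subsets <- function() {
  list(
    subset_spec("Bc", 0.043,
                c("CD20" = "hi", "HLA-DR" = "hi")),
    subset_spec("naive CD4 Tc", 0.253,
                c("CD3" = "hi", "CD4" = "hi", "CD45RA" = "hi")),
    subset_spec("memory CD4 Tc", 0.300,
                c("CD3" = "hi", "CD4" = "hi")),
    subset_spec("CD8 Tc", 0.200,
                c("CD3" = "hi", "CD8a" = "hi")),
    subset_spec("NKc", 0.050,
                c("CD56" = "hi", "CD16" = "hi")),
    subset_spec("cM", 0.057,
                c("CD14" = "hi", "CD61" = "hi", "CD11c" = "hi",
                  "HLA-DR" = "hi")),
    subset_spec("mDc", 0.087,
                c("CD11c" = "hi", "HLA-DR" = "hi")),
    subset_spec("pDc", 0.010,
                c("CD123" = "hi", "HLA-DR" = "hi")))
}

#' Default TNF stimulation response
#'
#' Mean shifts on the arcsinh scale applied to functional markers in the
#' stimulated condition: IkBa degradation (negative shift) together with
#' p-NFkB and p-p38 induction, strongest in the TNF-receptor-rich myeloid
#' compartment and weaker in lymphocytes.
#'
#' @return data.frame with columns `subset`, `marker`, `shift`.
#' @export
default_stimulation <- function() {
  myeloid <- c("cM", "mDc", "pDc")
  lymphoid <- c("naive CD4 Tc", "memory CD4 Tc", "CD8 Tc", "NKc", "Bc")
  rbind(
    expand.grid(subset = myeloid, marker = "IkBa", shift = -0.5,
                stringsAsFactors = FALSE),
    expand.grid(subset = myeloid, marker = "p-NFkB", shift = 0.6,
                stringsAsFactors = FALSE),
    expand.grid(subset = myeloid, marker = "p-p38", shift = 0.5,
                stringsAsFactors = FALSE),
    expand.grid(subset = lymphoid, marker = "IkBa", shift = -0.15,
                stringsAsFactors = FALSE),
    expand.grid(subset = lymphoid, marker = "p-NFkB", shift = 0.2,
                stringsAsFactors = FALSE),
    expand.grid(subset = lymphoid, marker = "p-p38", shift = 0.15,
                stringsAsFactors = FALSE))
}

#' Default QC-channel model
#'
#' Clean events draw each QC channel from N(100, 10). Doublet/debris
#' artifact events are shifted by `separation_sd` standard deviations in
#' event length, the two DNA intercalator channels and the acquisition
#' residual, mimicking aggregates and bare-DNA fragments.
#'
#' @param separation_sd shift of the artifact population, in clean-sd units.
#' @return list with `clean` and `debris` (each `mean`, `sd` named over the
#'   7 QC channels).
#' @export
default_qc_model <- function(separation_sd = 4) {
  qc <- panel_channels(default_panel(), "qc")
  clean_mean <- stats::setNames(rep(100, length(qc)), qc)
  sd <- stats::setNames(rep(10, length(qc)), qc)
  debris_mean <- clean_mean
  shifted <- c("Event_length", "Residual", "191Ir_DNA1", "193Ir_DNA2")
  debris_mean[shifted] <- debris_mean[shifted] + separation_sd * sd[shifted]
  list(clean = list(mean = clean_mean, sd = sd),
       debris = list(mean = debris_mean, sd = sd))
}

#' Full simulation configuration
#'
#' @param n_hd,n_ra number of healthy donors and patients (default 20/20).
#' @param events_per_sample events per individual per condition.
#' @param subsets list of `subset_spec`; proportions must sum to 1.
#' @param effects data.frame with columns `subset`, `marker`, `component`
#'   (`"basal"` or `"stim_response"`) and `delta`: arcsinh-scale shifts
#'   applied to the RA group. Basal deltas shift both conditions (so ratios
#'   are untouched); stim_response deltas shift only the stimulated
#'   condition.
#' @param stimulation data.frame (`subset`, `marker`, `shift`): stimulation
#'   shifts applied to both groups in the stim condition.
#' @param debris_fraction expected fraction of artifact events in [0, 1).
#' @param qc_model see [default_qc_model()].
#' @param between_individual_sd sd of per-individual, per-marker random
#'   intercepts shared by all of that individual's events and conditions.
#' @param cofactor arcsinh cofactor used to map simulated arcsinh values
#'   back to raw ion counts.
#' @param seed integer; fully determines the generated cohort.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_hd = 20, n_ra = 20, events_per_sample = 5000,
                              subsets = default_subsets(),
                              effects = NULL,
                              stimulation = default_stimulation(),
                              debris_fraction = 0.1,
                              qc_model = default_qc_model(),
                              between_individual_sd = 0.2,
                              cofactor = 5, seed = 1L) {
  props <- vapply(subsets, function(s) s$proportion, 0)
  if (abs(sum(props) - 1) > 1e-9)
    stop("subset proportions must sum to 1 (got ", sum(props), ")")
  subset_names <- vapply(subsets, function(s) s$name, "")
  if (anyDuplicated(subset_names) > 0) stop("subset names must be unique")
  fun_markers <- panel_markers(default_panel(), "functional")
  if (is.null(effects))
    effects <- data.frame(subset = character(), marker = character(),
                          component = character(), delta = numeric())
  stopifnot(all(effects$subset %in% subset_names),
            all(effects$marker %in% fun_markers),
            all(effects$component %in% c("basal", "stim_response")))
  stopifnot(all(stimulation$subset %in% subset_names),
            all(stimulation$marker %in% fun_markers))
  if (debris_fraction < 0 || debris_fraction >= 1)
    stop("debris_fraction must be in [0, 1)")
  if (between_individual_sd < 0) stop("between_individual_sd must be >= 0")
  structure(list(n_hd = n_hd, n_ra = n_ra,
                 events_per_sample = events_per_sample,
                 subsets = subsets, effects = effects,
                 stimulation = stimulation,
                 debris_fraction = debris_fraction, qc_model = qc_model,
                 between_individual_sd = between_individual_sd,
                 cofactor = cofactor, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Scenario with planted group effects
#'
#' Plants the disease-associated basal shifts this pipeline is designed to
#' recover: in the RA group, higher basal p-p38 and IkBa in memory CD4 T
#' cells, higher p-cJun in naive and memory CD4 T cells, higher p-NFkB and
#' lower CD86 in myeloid dendritic cells and classical monocytes. A smaller
#' stimulation-response component (scaled by `response_scale`) strengthens
#' the TNF-induced p-NFkB/p-p38 response in the same RA subsets so that
#' ratio features carry some, weaker, signal.
#'
#' @param effect_scale magnitude of each planted basal delta, arcsinh units.
#'   Zero degenerates to the null (no group difference) configuration.
#' @param response_scale magnitude of the planted stimulation-response
#'   deltas; defaults to a quarter of `effect_scale`.
#' @param ... further arguments passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
default_paper_scenario <- function(effect_scale = 1,
                                   response_scale = 0.25 * effect_scale,
                                   ...) {
  basal <- data.frame(
    subset = c("memory CD4 Tc", "memory CD4 Tc", "naive CD4 Tc",
               "memory CD4 Tc", "mDc", "cM", "mDc", "cM"),
    marker = c("p-p38", "IkBa", "p-cJun", "p-cJun", "p-NFkB", "p-NFkB",
               "CD86", "CD86"),
    component = "basal",
    delta = effect_scale * c(1, 1, 1, 1, 1, 1, -1, -1),
    stringsAsFactors = FALSE)
  resp <- data.frame(
    subset = c("memory CD4 Tc", "cM", "mDc"),
    marker = c("p-p38", "p-NFkB", "p-NFkB"),
    component = "stim_response",
    delta = response_scale * c(1, 1, 1),
    stringsAsFactors = FALSE)
  effects <- rbind(basal, resp)
  effects <- effects[effects$delta != 0, , drop = FALSE]
  simulation_config(effects = effects, ...)
}

# Per-subset mean/sd matrices over all marker channels, with group /
# condition deltas folded in.
subset_mean_matrix <- function(config, group, condition, panel) {
  marker_ch <- panel_channels(panel, c("phenotyping", "functional"))
  markers <- c(panel_markers(panel, "phenotyping"),
               panel_markers(panel, "functional"))
  S <- length(config$subsets)
  mu <- matrix(0, S, length(marker_ch),
               dimnames = list(vapply(config$subsets, `[[`, "", "name"),
                               markers))
  sd <- mu
  for (i in seq_len(S)) {
    s <- config$subsets[[i]]
    mu[i, names(s$phenotype_mean)] <- s$phenotype_mean
    sd[i, names(s$phenotype_mean)] <- s$pheno_sd
    mu[i, names(s$functional_mean)] <- s$functional_mean
    sd[i, names(s$functional_sd)] <- s$functional_sd
  }
  if (condition == "stim") {
    st <- config$stimulation
    for (r in seq_len(nrow(st)))
      mu[st$subset[r], st$marker[r]] <- mu[st$subset[r], st$marker[r]] +
        st$shift[r]
  }
  if (group == "RA") {
    ef <- config$effects
    active <- ef$component == "basal" |
      (ef$component == "stim_response" & condition == "stim")
    ef <- ef[active, , drop = FALSE]
    for (r in seq_len(nrow(ef)))
      mu[ef$subset[r], ef$marker[r]] <- mu[ef$subset[r], ef$marker[r]] +
        ef$delta[r]
  }
  list(mu = mu, sd = sd, channels = marker_ch)
}

#' Simulate a paired-condition cohort
#'
#' Generates one basal and one stimulated event table per individual.
#' Marker values are drawn as Gaussians on the arcsinh scale (subset
#' template + group/stimulation deltas + the individual's random intercept)
#' and mapped back to the raw scale via `cofactor * sinh(x)`, truncated at
#' zero. Artifact (doublet/debris) events draw their QC channels from the
#' shifted artifact model and their marker values by resampling the
#' sample's clean events, then the event order is shuffled.
#'
#' @param config a `simulation_config`.
#' @return list with `manifest` (a `cohort_manifest`), `tables` (list of
#'   raw `event_table`, one per manifest record) and `truth` (per-table
#'   event labels, realized proportions and the applied effect list).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  panel <- default_panel(cofactor = config$cofactor)
  qc_ch <- panel_channels(panel, "qc")
  subset_names <- vapply(config$subsets, `[[`, "", "name")
  props <- vapply(config$subsets, `[[`, 0, "proportion")
  markers_all <- c(panel_markers(panel, "phenotyping"),
                   panel_markers(panel, "functional"))

  set.seed(config$seed)
  ids <- c(sprintf("HD%02d", seq_len(config$n_hd)),
           sprintf("RA%02d", seq_len(config$n_ra)))
  groups <- rep(c("HD", "RA"), c(config$n_hd, config$n_ra))
  records <- data.frame(
    individual_id = rep(ids, each = 2),
    group = rep(groups, each = 2),
    condition = rep(c("basal", "stim"), length(ids)),
    stringsAsFactors = FALSE)

  tables <- vector("list", nrow(records))
  labels <- vector("list", nrow(records))
  realized <- matrix(0, length(ids), length(subset_names),
                     dimnames = list(ids, subset_names))

  mean_cache <- list()
  for (g in c("HD", "RA")) for (cond in c("basal", "stim"))
    mean_cache[[paste(g, cond)]] <- subset_mean_matrix(config, g, cond, panel)

  n_ev <- config$events_per_sample
  for (i in seq_along(ids)) {
    intercept <- stats::rnorm(length(markers_all),
                              sd = config$between_individual_sd)
    names(intercept) <- markers_all
    for (cond in c("basal", "stim")) {
      mm <- mean_cache[[paste(groups[i], cond)]]
      n_debris <- stats::rbinom(1L, n_ev, config$debris_fraction)
      n_clean <- n_ev - n_debris
      lab <- sample.int(length(subset_names), n_clean, replace = TRUE,
                        prob = props)
      mu <- mm$mu[lab, , drop = FALSE] +
        matrix(intercept, n_clean, length(markers_all), byrow = TRUE)
      vals <- mu + matrix(stats::rnorm(n_clean * length(markers_all)),
                          n_clean) * mm$sd[lab, , drop = FALSE]
      raw_markers <- pmax(sinh(vals) * config$cofactor, 0)
      colnames(raw_markers) <- mm$channels
      qc_clean <- vapply(qc_ch, function(ch)
        stats::rnorm(n_clean, config$qc_model$clean$mean[ch],
                     config$qc_model$clean$sd[ch]), numeric(n_clean))
      m <- cbind(qc_clean, raw_markers)
      colnames(m) <- c(qc_ch, mm$channels)
      debris_flag <- rep(FALSE, n_clean)
      sub_lab <- subset_names[lab]
      if (n_debris > 0) {
        qc_debris <- vapply(qc_ch, function(ch)
          stats::rnorm(n_debris, config$qc_model$debris$mean[ch],
                       config$qc_model$debris$sd[ch]), numeric(n_debris))
        if (n_debris == 1L) qc_debris <- matrix(qc_debris, nrow = 1L)
        mk_debris <- vapply(seq_along(mm$channels), function(j)
          raw_markers[sample.int(n_clean, n_debris, replace = TRUE), j],
          numeric(n_debris))
        if (n_debris == 1L) mk_debris <- matrix(mk_debris, nrow = 1L)
        dm <- cbind(qc_debris, mk_debris)
        colnames(dm) <- colnames(m)
        m <- rbind(m, dm)
        debris_flag <- c(debris_flag, rep(TRUE, n_debris))
        sub_lab <- c(sub_lab, rep(NA_character_, n_debris))
      }
      m[, qc_ch] <- pmax(m[, qc_ch], 0)
      ord <- sample.int(nrow(m))
      m <- m[ord, , drop = FALSE]
      debris_flag <- debris_flag[ord]
      sub_lab <- sub_lab[ord]
      idx <- which(records$individual_id == ids[i] &
                     records$condition == cond)
      tables[[idx]] <- event_table(m, panel, ids[i], groups[i], cond)
      labels[[idx]] <- data.frame(subset = sub_lab, debris = debris_flag,
                                  stringsAsFactors = FALSE)
      tt <- table(factor(sub_lab, levels = subset_names))
      realized[ids[i], ] <- realized[ids[i], ] + as.numeric(tt)
    }
  }
  realized <- realized / rowSums(realized)

  truth <- list(labels = labels, group = stats::setNames(groups, ids),
                realized_proportions = realized, effects = config$effects)
  list(manifest = cohort_manifest(records), tables = tables, truth = truth)
}
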