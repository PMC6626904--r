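#' Marker panel definition
#'
#' A panel maps instrument channel names (metal_marker dialect, e.g.
#' `"156Gd_p-p38"`) to a role in the pipeline: `qc` channels drive doublet /
#' debris cleanup, `phenotyping` markers drive clustering, and `functional`
#' markers become classification features.
#'
#' @param channels data.frame with columns `channel` (unique channel name),
#'   `marker` (short marker name) and `role` (one of `"qc"`,
#'   `"phenotyping"`, `"functional"`).
#' @param cofactor positive arcsinh scaling divisor applied to marker
#'   channels (never to qc channels). The CyTOF convention of 5 is the
#'   default.
#' @return An object of class `panel_definition`.
#' @export
panel_definition <- function(channels, cofactor = 5) {
  stopifnot(is.data.frame(channels),
            all(c("channel", "marker", "role") %in% names(channels)))
  channels$channel <- as.character(channels$channel)
  channels$marker <- as.character(channels$marker)
  channels$role <- as.character(channels$role)
  if (anyDuplicated(channels$channel) > 0)
    stop("panel channel names must be unique")
  if (!all(channels$role %in% c("qc", "phenotyping", "functional")))
    stop("panel roles must be one of 'qc', 'phenotyping', 'functional'")
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
    stop("cofactor must be a single positive number")
  structure(list(channels = channels, cofactor = cofactor),
            class = "panel_definition")
}

#' Default 28-channel panel
#'
#' Seven quality-control channels (event geometry, Gaussian acquisition
#' parameters and the two iridium DNA intercalators), twelve surface
#' phenotyping markers used for clustering, and nine functional (signaling)
#' markers used as classification features. CD45 is not part of the
#' clustering marker set and is therefore absent from the default panel.
#'
#' @param cofactor arcsinh cofactor, default 5.
#' @return A `panel_definition` with 28 channels.
#' @export
default_panel <- function(cofactor = 5) {
  qc <- c("Event_length", "Center", "Offset", "Width", "Residual",
          "191Ir_DNA1", "193Ir_DNA2")
  pheno <- c("147Sm_CD20", "170Er_CD3", "145Nd_CD4", "146Nd_CD8a",
             "169Tm_CD45RA", "176Yb_CD56", "148Nd_CD16", "160Gd_CD14",
             "209Bi_CD61", "159Tb_CD11c", "151Eu_CD123", "174Yb_HLA-DR")
  fun <- c("142Nd_Caspase3", "156Gd_p-p38", "152Sm_p-Akt", "167Er_p-cJun",
           "166Er_p-NFkB", "164Dy_IkBa", "155Gd_CD120a", "165Ho_CD120b",
           "150Nd_CD86")
  strip_metal <- function(x) sub("^[0-9]+[A-Za-z]+_", "", x)
  channels <- data.frame(
    channel = c(qc, pheno, fun),
    marker = c(qc, strip_metal(pheno), strip_metal(fun)),
    role = rep(c("qc", "phenotyping", "functional"),
               c(length(qc), length(pheno), length(fun))),
    stringsAsFactors = FALSE)
  panel_definition(channels, cofactor = cofactor)
}

#' @export
print.panel_definition <- function(x, ...) {
  tab <- table(x$channels$role)
  cat(sprintf("panel_definition: %d channels (%s), cofactor %g\n",
              nrow(x$channels),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              x$cofactor))
  invisible(x)
}

#' Panel channel and marker accessors
#'
#' @param panel a `panel_definition`.
#' @param role optional role filter (`"qc"`, `"phenotyping"`,
#'   `"functional"`); `panel_markers()` requires it.
#' @return Character vector of channel names / marker names.
#' @export
panel_channels <- function(panel, role = NULL) {
  ch <- panel$channels
  if (is.null(role)) ch$channel else ch$channel[ch$role %in% role]
}

#' @rdname panel_channels
#' @export
panel_markers <- function(panel, role) {
  ch <- panel$channels
  ch$marker[ch$role %in% role]
}

#' Cohort manifest
#'
#' The manifest records which individual, group and condition each event
#' file belongs to. Each (individual, condition) pair may occur at most
#' once; paired-condition feature models additionally require every
#' individual to be present in both conditions.
#'
#' @param records data.frame with columns `individual_id`, `group`
#'   (`"HD"` or `"RA"`), `condition` (`"basal"` or `"stim"`), and
#'   optionally `source` (file path).
#' @return An object of class `cohort_manifest`.
#' @export
cohort_manifest <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("individual_id", "group", "condition") %in% names(records)))
  records$individual_id <- as.character(records$individual_id)
  records$group <- as.character(records$group)
  records$condition <- as.character(records$condition)
  if (!all(records$group %in% c("HD", "RA")))
    stop("group must be 'HD' or 'RA'")
  if (!all(records$condition %in% c("basal", "stim")))
    stop("condition must be 'basal' or 'stim'")
  key <- paste(records$individual_id, records$condition)
  if (anyDuplicated(key) > 0)
    stop("each (individual_id, condition) pair may occur at most once")
  grp <- tapply(records$group, records$individual_id,
                function(g) length(unique(g)))
  if (any(grp > 1))
    stop("an individual cannot belong to two groups")
  if (!"source" %in% names(records)) records$source <- NA_character_
  structure(list(records = records), class = "cohort_manifest")
}

#' @export
print.cohort_manifest <- function(x, ...) {
  r <- x$records
  cat(sprintf("cohort_manifest: %d records, %d individuals (%d HD, %d RA)\n",
              nrow(r), length(unique(r$individual_id)),
              length(unique(r$individual_id[r$group == "HD"])),
              length(unique(r$individual_id[r$group == "RA"]))))
  invisible(x)
}

#' Check that every individual is present in both conditions
#'
#' @param manifest a `cohort_manifest`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_paired <- function(manifest) {
  r <- manifest$records
  n_cond <- tapply(r$condition, r$individual_id,
                   function(x) length(unique(x)))
  bad <- names(n_cond)[n_cond < 2]
  if (length(bad))
    stop("individuals missing a condition: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}
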