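#' Generate the in vitro cardiac microtissue sample design
#'
#' Builds the full factorial design of three anthracyclines (doxorubicin,
#' epirubicin, idarubicin) at a therapeutic and a toxic dose, sampled at seven
#' exposure timepoints (2, 8, 24, 72, 168, 240, 336 h), plus untreated control
#' microtissues at every timepoint. The toxic idarubicin arm is truncated at
#' 168 h (massive cell death precludes later harvests), and with three
#' replicates its 2 h and 24 h cells carry only two replicates; with the
#' default `n_replicates = 3` the design therefore has exactly 139 samples
#' (21 control + 42 DOX + 42 EPI + 34 IDA).
#'
#' @param n_replicates Replicates per design cell (positive integer).
#' @param ida_toxic_reduced If `TRUE` (default), cap the toxic-idarubicin
#'   replicates at 2 for the 2 h and 24 h timepoints when `n_replicates >= 3`.
#' @param seed Unused (the design is deterministic); accepted so all
#'   generators share a signature.
#' @return A tibble with columns `sample_id`, `dataset_kind`, `compound`,
#'   `dose`, `timepoint_h`, `replicate`, `patient_group`.
#' @examples
#' nrow(generate_invitro_design(3)) # 139
#' @export
generate_invitro_design <- function(n_replicates = 3, ida_toxic_reduced = TRUE,
                                    seed = NULL) {
  if (!is.numeric(n_replicates) || length(n_replicates) != 1 ||
      n_replicates < 1 || n_replicates != floor(n_replicates)) {
    abort("`n_replicates` must be a positive integer")
  }
  timepoints <- c(2, 8, 24, 72, 168, 240, 336)
  grid <- tidyr::expand_grid(
    compound = c("DOX", "EPI", "IDA"),
    dose = c("therapeutic", "toxic"),
    timepoint_h = timepoints
  )
  ctrl <- tibble::tibble(compound = "none", dose = "none",
                         timepoint_h = timepoints)
  grid <- dplyr::bind_rows(ctrl, grid)
  # IDA toxic arm truncated at 168 h
  grid <- dplyr::filter(grid,
    !(.data$compound == "IDA" & .data$dose == "toxic" & .data$timepoint_h > 168))
  grid$n_rep <- n_replicates
  if (ida_toxic_reduced && n_replicates >= 3) {
    red <- grid$compound == "IDA" & grid$dose == "toxic" &
      grid$timepoint_h %in% c(2, 24)
    grid$n_rep[red] <- 2L
  }
  out <- tidyr::uncount(grid, weights = .data$n_rep, .id = "replicate")
  arm <- ifelse(out$compound == "none", "CTRL",
                paste0(out$compound, "_", substr(out$dose, 1, 3)))
  out$sample_id <- sprintf("%s_%03dh_r%d", arm, out$timepoint_h, out$replicate)
  tibble::tibble(
    sample_id = out$sample_id,
    dataset_kind = "invitro",
    compound = out$compound,
    dose = out$dose,
    timepoint_h = out$timepoint_h,
    replicate = as.integer(out$replicate),
    patient_group = NA_character_
  )
}

#' Generate the human cardiac biopsy sample design
#'
#' Emulates the biopsy cohort used for network analysis: heart-failure
#' patients split into a no-cancer control group, a group treated with
#' anthracyclines, and a group treated for cancer without anthracyclines.
#' Defaults reproduce the 16-biopsy design (8 + 6 + 2).
#'
#' @param n_control,n_ant,n_nonant Patients per group.
#' @param seed Unused (deterministic); kept for signature symmetry.
#' @return A design tibble with the same columns as
#'   [generate_invitro_design()], with `patient_group` filled and
#'   compound/dose/timepoint absent.
#' @export
generate_biopsy_design <- function(n_control = 8, n_ant = 6, n_nonant = 2,
                                   seed = NULL) {
  stopifnot(n_control >= 1, n_ant >= 0, n_nonant >= 0)
  groups <- rep(c("control", "ant_treated", "nonant_treated"),
                times = c(n_control, n_ant, n_nonant))
  rep_id <- stats::ave(seq_along(groups), groups, FUN = seq_along)
  short <- c(control = "CtrlPat", ant_treated = "ANTPat",
             nonant_treated = "NonANTPat")
  tibble::tibble(
    sample_id = sprintf("%s_%02d", short[groups], rep_id),
    dataset_kind = "biopsy",
    compound = "none",
    dose = "none",
    timepoint_h = NA_real_,
    replicate = as.integer(rep_id),
    patient_group = groups
  )
}

#' Split a design into treated and control sample ids
#'
#' For in vitro designs treated samples are those exposed to any compound;
#' for biopsy designs treated samples are the anthracycline-treated patients
#' and controls are the no-cancer patients (other groups are left out).
#'
#' @param design A design tibble.
#' @return A list with character vectors `treated` and `control`.
#' @export
treatment_groups <- function(design) {
  stopifnot(all(c("sample_id", "dataset_kind") %in% names(design)))
  if (all(design$dataset_kind == "biopsy")) {
    list(
      treated = design$sample_id[design$patient_group == "ant_treated"],
      control = design$sample_id[design$patient_group == "control"]
    )
  } else {
    list(
      treated = design$sample_id[design$compound != "none"],
      control = design$sample_id[design$compound == "none"]
    )
  }
}
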