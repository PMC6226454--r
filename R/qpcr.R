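# Validate a CT table: long tibble of replicate CT measurements.
validate_ct <- function(ct) {
  need <- c("gene_id", "treatment", "bio_rep", "tech_rep",
            "ct_target", "ct_reference")
  stopifnot(all(need %in% names(ct)))
  if (any(!is.finite(ct$ct_reference)))
    stop("missing reference CT", call. = FALSE)
  if (any(!is.finite(ct$ct_target)))
    stop("missing target CT", call. = FALSE)
  if (any(ct$ct_target <= 0 | ct$ct_target >= 45) ||
      any(ct$ct_reference <= 0 | ct$ct_reference >= 45))
    stop("CT values must lie in (0, 45)", call. = FALSE)
  ct
}

#' Per-biological-replicate delta-CT values
#'
#' Technical replicates are averaged first; then
#' `dCT = CT_target - CT_reference` per (gene, treatment, biological
#' replicate).
#'
#' @param ct CT tibble with columns `gene_id`, `treatment`, `bio_rep`,
#'   `tech_rep`, `ct_target`, `ct_reference`.
#' @return Tibble with `gene_id`, `treatment`, `bio_rep`, `delta_ct`.
#' @export
delta_ct <- function(ct) {
  ct <- validate_ct(ct)
  ct |>
    dplyr::group_by(.data$gene_id, .data$treatment, .data$bio_rep) |>
    dplyr::summarise(
      delta_ct = mean(.data$ct_target) - mean(.data$ct_reference),
      .groups = "drop")
}

#' Fold change from mean delta-CT values
#'
#' `2^-(dCT_treated - dCT_control)`, the Livak relative-quantification
#' formula.
#'
#' @param delta_ct_treated,delta_ct_control Mean delta-CT of treated and
#'   control samples.
#' @return Fold change (1 = unchanged; 4 means ddCT = -2).
#' @export
#' @examples
#' fold_change(3, 5) # ddCT = -2 -> 4
fold_change <- function(delta_ct_treated, delta_ct_control) {
  stopifnot(is.finite(delta_ct_treated), is.finite(delta_ct_control))
  2^(-(delta_ct_treated - delta_ct_control))
}

#' Regulation calls from replicate CT data
#'
#' For each gene and non-control treatment, biological-replicate delta-CT
#' values are compared with the control's by a two-sample t-test (Student's
#' equal-variance test by default, matching the study design; Welch via
#' `welch = TRUE`), and the fold change `2^-ddCT` is computed from the
#' means. A gene is called `up` when fold >= `fold_min` and p < `alpha`,
#' `down` when fold <= 1/`fold_min` and p < `alpha`, otherwise `unchanged`.
#' `fold_min = 1` reproduces significance-only calling.
#'
#' @param ct CT tibble (see [delta_ct()]); must contain the control.
#' @param alpha Significance level (default 0.05).
#' @param fold_min Minimum fold change for an up/down call (default 2).
#' @param control Control treatment label (default `"control"`).
#' @param welch Use the Welch t-test instead of Student's (default FALSE).
#' @param fdr Apply Benjamini-Hochberg correction across all tests before
#'   calling (default FALSE, matching significance-only practice).
#' @return Tibble with `gene_id`, `treatment`, `fold`, `p_value`, `call`.
#' @export
regulation_calls <- function(ct, alpha = 0.05, fold_min = 2,
                             control = "control", welch = FALSE,
                             fdr = FALSE) {
  d <- delta_ct(ct)
  if (!control %in% d$treatment)
    stop("control treatment '", control, "' not present", call. = FALSE)
  nrep <- d |>
    dplyr::count(.data$gene_id, .data$treatment)
  if (any(nrep$n < 2))
    stop("need >= 2 biological replicates per gene and treatment",
         call. = FALSE)
  ctrl <- d[d$treatment == control, ]
  trt <- d[d$treatment != control, ]
  out <- trt |>
    dplyr::group_by(.data$gene_id, .data$treatment) |>
    dplyr::summarise(
      fold = fold_change(mean(.data$delta_ct),
                         mean(ctrl$delta_ct[ctrl$gene_id ==
                                              .data$gene_id[1]])),
      p_value = stats::t.test(
        .data$delta_ct,
        ctrl$delta_ct[ctrl$gene_id == .data$gene_id[1]],
        var.equal = !welch)$p.value,
      .groups = "drop")
  if (fdr) out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  out$call <- dplyr::case_when(
    out$p_value < alpha & out$fold >= fold_min ~ "up",
    out$p_value < alpha & out$fold <= 1 / fold_min ~ "down",
    TRUE ~ "unchanged")
  out
}
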