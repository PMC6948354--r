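#' ADME screen of herb components
#'
#' Screens raw components to active components by oral bioavailability (OB)
#' and drug-likeness (DL) cutoffs. A component is active iff
#' `ob >= ob_min` and `dl >= dl_min` (both comparisons inclusive), or its id
#' is in the literature-rescue whitelist `rescue_ids` — a curated list of
#' components kept despite failing the ADME cutoffs because of reported
#' therapeutic effects. Missing (NA) OB or DL fails the cutoffs, so such
#' components survive only via rescue.
#'
#' @param components Component `data.frame` (see [read_component_table()]).
#' @param ob_min OB cutoff in percent; the conventional screen uses 30.
#' @param dl_min DL cutoff (dimensionless); the conventional screen uses 0.18.
#' @param rescue_ids Character vector of component ids to rescue. Ids not
#'   present in `components` produce a warning, not an error.
#' @return A list with `active` (the screened `data.frame`, rescued rows
#'   flagged `rescued = TRUE`) and `report` (counts of `input`, `kept`,
#'   `passed_adme`, `rescued`, `dropped`, and the thresholds applied).
#' @export
filter_components <- function(components, ob_min = 30, dl_min = 0.18,
                              rescue_ids = character()) {
  stopifnot(is.finite(ob_min), is.finite(dl_min))
  rescue_ids <- unique(as.character(rescue_ids))
  unknown <- setdiff(rescue_ids, components$component_id)
  if (length(unknown) > 0) {
    warning("rescue id(s) not present in input: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  passes <- !is.na(components$ob) & !is.na(components$dl) &
    components$ob >= ob_min & components$dl >= dl_min
  in_rescue <- components$component_id %in% rescue_ids
  keep <- passes | in_rescue
  active <- components[keep, , drop = FALSE]
  active$rescued <- active$rescued | in_rescue[keep]
  rownames(active) <- NULL
  list(
    active = active,
    report = list(
      input = nrow(components),
      kept = nrow(active),
      passed_adme = sum(passes),
      rescued = sum(in_rescue & !passes),
      dropped = nrow(components) - nrow(active),
      ob_min = ob_min, dl_min = dl_min
    )
  )
}
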