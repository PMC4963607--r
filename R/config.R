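#' Load an agent parameter set from a YAML config file
#'
#' The file holds either a preset name (`preset: learner`) or any subset
#' of [agent_params()] fields, which override the chosen preset's
#' defaults (`preset: custom` when omitted).
#'
#' @param path Path to a YAML file.
#' @return An [agent_params()] object.
#' @export
read_agent_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  preset <- cfg$preset %||% "custom"
  cfg$preset <- NULL
  known <- setdiff(names(formals(agent_params)), "preset")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown agent field(s): ", paste(bad, collapse = ", "))
  }
  do.call(agent_params, c(list(preset = preset), cfg))
}

#' Load a cohort specification from a YAML config file
#'
#' Top-level fields mirror [cohort_spec()] arguments; the `cells` block
#' defines per-outcome condition-by-time means and SDs:
#'
#' ```yaml
#' n_per_condition: 26
#' correlation: 0.6
#' cells:
#'   heq_total:
#'     training: {means: [36.96, 42.42], sds: [8.45, 9.98]}
#'     waitlist: {means: [39.58, 35.88], sds: [9.68, 11.24]}
#' ```
#'
#' Outcomes absent from `cells` fall back to the package defaults when
#' `merge_defaults` is `TRUE`.
#'
#' @param path Path to a YAML file.
#' @param merge_defaults Start from [default_outcome_cells()] and
#'   override, rather than requiring every outcome in the file.
#' @return A [cohort_spec()].
#' @export
read_cohort_spec <- function(path, merge_defaults = TRUE) {
  cfg <- yaml::read_yaml(path)
  outcomes <- if (merge_defaults) default_outcome_cells() else list()
  for (nm in names(cfg$cells)) {
    cell <- cfg$cells[[nm]]
    for (cond in c("training", "waitlist")) {
      if (is.null(cell[[cond]])) {
        stop("cells for '", nm, "' lack condition '", cond, "'")
      }
    }
    dn <- list(c("training", "waitlist"), c("t1", "t2"))
    outcomes[[nm]] <- list(
      means = matrix(c(cell$training$means, cell$waitlist$means), 2, 2,
                     byrow = TRUE, dimnames = dn),
      sds = matrix(c(cell$training$sds, cell$waitlist$sds), 2, 2,
                   byrow = TRUE, dimnames = dn)
    )
  }
  cfg$cells <- NULL
  known <- setdiff(names(formals(cohort_spec)), "outcomes")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown cohort field(s): ", paste(bad, collapse = ", "))
  }
  do.call(cohort_spec, c(list(outcomes = outcomes), cfg))
}
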