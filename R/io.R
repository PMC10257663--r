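#' Built-in example drug-response profiles
#'
#' Reference parameterizations used throughout the examples and tests,
#' anchored to the untreated AU565-like condition: mean G1 and S-G2 durations
#' of 22.3 hours each, giving per-part control rates alpha = 8/22.3 and
#' beta = 20/22.3 per hour, with no death in control.
#'
#' \itemize{
#'   \item \code{g1_blocker}: a lapatinib/palbociclib-like pure G1 inhibitor
#'     (EC50 50 nM, k 2) whose saturating effect nearly halts G1 progression,
#'     producing a cytostatic plateau at high dose.
#'   \item \code{g1_blocker_b}: a second, independent G1 inhibitor (EC50
#'     100 nM) for same-phase combination studies.
#'   \item \code{s_phase_drug}: a gemcitabine-like agent (EC50 5 nM, k 2)
#'     that slows S-G2 progression (saturating beta 0.434/h, lengthening
#'     S-G2 toward ~38 h at 10 nM) and adds S-G2 death (saturating gamma2
#'     0.03/h), i.e. mixed cytostatic/cytotoxic.
#' }
#'
#' @param structure a \code{\link{phase_structure}}
#' @return named list of \code{\link{drug_response_profile}}s plus
#'   \code{control} (\code{rate_set}) and \code{initial_g1_fraction}
#' @export
example_profiles <- function(structure = phase_structure()) {
  ctrl <- rate_set(alpha = structure$n_g1 / 22.3,
                   beta = structure$n_sg2 / 22.3,
                   gamma1 = 0, gamma2 = 0, structure = structure)
  list(
    control = ctrl,
    initial_g1_fraction = 0.75,
    g1_blocker = drug_response_profile(
      "g1_blocker", ctrl, ec50 = 50, k = 2,
      emax_alpha = 0.02 * ctrl$alpha),
    g1_blocker_b = drug_response_profile(
      "g1_blocker_b", ctrl, ec50 = 100, k = 2,
      emax_alpha = 0.02 * ctrl$alpha),
    s_phase_drug = drug_response_profile(
      "s_phase_drug", ctrl, ec50 = 5, k = 2,
      emax_beta = 0.434, emax_gamma2 = 0.03)
  )
}

#' Serialize model objects to plain lists (for YAML configs)
#'
#' @param x a \code{rate_set} or \code{drug_response_profile}
#' @return a plain list round-trippable through YAML
#' @export
as_config_list <- function(x) UseMethod("as_config_list")

#' @export
as_config_list.rate_set <- function(x) {
  s <- x$structure
  list(structure = list(g1_parts = s$g1_parts,
                        g1_subphases_per_part = s$g1_subphases_per_part,
                        sg2_parts = s$sg2_parts,
                        sg2_subphases_per_part = s$sg2_subphases_per_part),
       units = "1/hour",
       alpha = x$alpha, beta = x$beta, gamma1 = x$gamma1, gamma2 = x$gamma2)
}

#' @export
as_config_list.drug_response_profile <- function(x) {
  list(drug_name = x$drug_name, ec50_nM = x$ec50, k = x$k,
       control_rates = as_config_list(x$control_rates),
       emax = x$emax)
}

#' Rebuild model objects from config lists
#' @param lst a list produced by \code{\link{as_config_list}} (or hand-written
#'   YAML of the same shape)
#' @return the corresponding model object
#' @export
rate_set_from_list <- function(lst) {
  s <- do.call(phase_structure, lst$structure)
  rate_set(lst$alpha, lst$beta, lst$gamma1, lst$gamma2, structure = s)
}

#' @rdname rate_set_from_list
#' @export
profile_from_list <- function(lst) {
  ctrl <- rate_set_from_list(lst$control_rates)
  drug_response_profile(lst$drug_name, ctrl, ec50 = lst$ec50_nM, k = lst$k,
                        emax_alpha = lst$emax$alpha, emax_beta = lst$emax$beta,
                        emax_gamma1 = lst$emax$gamma1,
                        emax_gamma2 = lst$emax$gamma2)
}

#' Read and write the package's tabular formats
#'
#' Trajectories use columns \code{time_h, g1, sg2, total, dead_cum};
#' population tables use
#' \code{drug, concentration, replicate, time_h, count_norm, frac_g1};
#' lineage tables use the \code{\link{simulate_cells}} columns.
#'
#' @param x object to write
#' @param path CSV path
#' @name lct_io
#' @export
write_trajectory_csv <- function(x, path) {
  utils::write.csv(x[, c("time_h", "g1", "sg2", "total", "dead_cum")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname lct_io
#' @export
write_population_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname lct_io
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("drug", "concentration", "replicate", "time_h", "count_norm", "frac_g1")
  if (!all(need %in% names(df)))
    stop("population CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname lct_io
#' @export
write_lineage_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname lct_io
#' @param rates optional \code{\link{rate_set}} to reattach
#' @export
read_lineage_csv <- function(path, rates = NULL) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "parent_id", "birth_time", "g1s_time", "end_time",
            "fate", "phase_at_end", "birth_phase", "weight")
  if (!all(need %in% names(df)))
    stop("lineage CSV must have columns: ", paste(need, collapse = ", "))
  class(df) <- c("cell_records", "data.frame")
  attr(df, "t_max") <- max(df$end_time)
  attr(df, "rates") <- rates
  df
}

#' Write and read structured YAML configuration documents
#'
#' Thin wrappers around the yaml package that keep full numeric precision,
#' so rate sets and profiles round-trip exactly enough for reproducibility.
#'
#' @param x list to serialize (e.g. from \code{\link{as_config_list}})
#' @param path YAML file path
#' @return \code{read_config} returns the parsed list
#' @export
write_config <- function(x, path) {
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)

write_manifest <- function(path, inputs = character(), seed = NULL) {
  man <- list(
    package = "lctcycle",
    version = as.character(utils::packageVersion("lctcycle")),
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
    seed = seed,
    input_md5 = if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  )
  yaml::write_yaml(man, path)
  invisible(path)
}
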