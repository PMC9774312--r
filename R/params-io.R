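#' Read an actuator parameter file
#'
#' YAML file with blocks `gas`, `regulator`, `cylinder`, `chest`, `pid`
#' (SI units throughout); missing fields fall back to the documented
#' defaults of the corresponding constructor.
#'
#' @param path YAML file.
#' @return List with elements `gas`, `reg`, `cyl`, `chest`, `gains`.
#' @export
read_actuator_params <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, block) do.call(ctor, lapply(block, as_num))
  list(gas = build(gas_constants, y$gas),
       reg = build(regulator_params, y$regulator),
       cyl = build(cylinder_params, y$cylinder),
       chest = build(chest_params, y$chest),
       gains = build(pid_gains, y$pid))
}

#' Shipped actuator configuration
#'
#' Reads `actuator_default.yaml` from the package's `extdata`: the
#' documented 50 mm-stroke prototype configuration (gas, regulator,
#' cylinder, chest and PID blocks).
#'
#' @param path parameter YAML file; default the shipped one.
#' @return As [read_actuator_params()].
#' @export
default_actuator <- function(path = system.file("extdata",
                                                "actuator_default.yaml",
                                                package = "cprsim")) {
  read_actuator_params(path)
}

# YAML floats with unsigned exponents ("4.5e5") arrive as strings;
# coerce anything that parses as a number
as_num <- function(x) {
  if (is.character(x) && !is.na(suppressWarnings(as.numeric(x))))
    as.numeric(x) else x
}

#' Read a circulation topology file
#'
#' YAML file with a `compartments` list (name, C, P0, intrathoracic,
#' pulmonary), an `edges` list (from, to, R, valve), a `sources` block
#' ([pump_source_params()] fields) and a `roles` block naming the metric
#' extraction points.
#'
#' @param path YAML file.
#' @return A [circulation_network()].
#' @export
read_circulation <- function(path) {
  y <- yaml::read_yaml(path)
  comp <- do.call(rbind, lapply(y$compartments, function(cc)
    data.frame(name = cc$name, C = as_num(cc$C), P0 = as_num(cc$P0),
               intrathoracic = isTRUE(cc$intrathoracic),
               pulmonary = isTRUE(cc$pulmonary))))
  edges <- do.call(rbind, lapply(y$edges, function(e)
    data.frame(from = e$from, to = e$to, R = as_num(e$R),
               valve = isTRUE(e$valve))))
  sources <- do.call(pump_source_params, lapply(y$sources, as_num))
  roles <- lapply(y$roles, unlist)
  circulation_network(comp, edges, sources, roles)
}
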