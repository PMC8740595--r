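#' Physical parameters of the gut flow model
#'
#' Bundles the constants describing a one-dimensional segment of the colon
#' lumen: bacteria are carried passively by a net flow and mixed by an
#' effective diffusion, and grow on a single inflowing food source with
#' Monod (saturating) kinetics.  Units are fixed package-wide: lengths in
#' cm, times in h, food concentrations in mM, bacteria as counts per cm^3,
#' so that `S * integral(B dx)` is a genuine bacterial count.
#'
#' The defaults are a reference parameter set for a colon-like regime with
#' strongly spatially dependent food and bacterial concentration profiles
#' (a 6 cm segment at v = 0.5 cm/h, D = 0.2 cm^2/h).
#'
#' @param v Flow velocity (cm/h).
#' @param D Effective diffusion coefficient (cm^2/h).
#' @param r Maximal division rate (1/h).
#' @param k Monod constant: food concentration at half-maximal growth (mM).
#' @param vFin Food inflow rate at the entrance (mM cm/h).  The inflowing
#'   food concentration is `Fin = vFin / v`.
#' @param alpha Yield: bacteria produced per cm^3 and per mM of food
#'   consumed (bacteria cm^-3 / mM).
#' @param L Length of the gut segment (cm).
#' @param S Cross-section area (cm^2).
#' @return An object of class `gut_params`.
#' @examples
#' p <- gut_parameters()
#' food_inflow_conc(p)  # Fin = vFin / v = 2 mM
#' @export
gut_parameters <- function(v = 0.5, D = 0.2, r = 0.42, k = 0.1, vFin = 1,
                           alpha = 6.13e8, L = 6, S = 1) {
  make_parameters(list(v = v, D = D, r = r, k = k, vFin = vFin,
                       alpha = alpha, L = L, S = S))
}

#' Validate a parameter configuration
#'
#' Builds a [gut_parameters()] object from a flat key-value map, typically
#' read from a YAML/JSON config file.  Validation is total: all eight
#' physical keys must be present, numeric, finite and strictly positive,
#' and unknown keys are rejected (no silent defaults for physical
#' constants).
#'
#' @param config Named list with exactly the keys
#'   `v, D, r, k, vFin, alpha, L, S`.
#' @return An object of class `gut_params`.
#' @export
make_parameters <- function(config) {
  keys <- c("v", "D", "r", "k", "vFin", "alpha", "L", "S")
  if (is.null(names(config)) || any(names(config) == ""))
    stop("configuration must be a fully named list", call. = FALSE)
  unknown <- setdiff(names(config), keys)
  if (length(unknown) > 0)
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(keys, names(config))
  if (length(missing) > 0)
    stop("missing parameter key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (key in keys) {
    val <- config[[key]]
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val))
      stop("parameter '", key, "' must be a single finite number",
           call. = FALSE)
    if (val <= 0)
      stop("parameter '", key, "' must be strictly positive (got ",
           val, ")", call. = FALSE)
  }
  p <- lapply(config[keys], as.numeric)
  class(p) <- "gut_params"
  p
}

#' @export
print.gut_params <- function(x, ...) {
  cat("Gut flow model parameters\n")
  cat(sprintf("  v     = %g cm/h (flow velocity)\n", x$v))
  cat(sprintf("  D     = %g cm^2/h (effective diffusion)\n", x$D))
  cat(sprintf("  r     = %g 1/h (maximal growth rate)\n", x$r))
  cat(sprintf("  k     = %g mM (Monod constant)\n", x$k))
  cat(sprintf("  vFin  = %g mM cm/h (food inflow rate)\n", x$vFin))
  cat(sprintf("  alpha = %g bacteria cm^-3/mM (yield)\n", x$alpha))
  cat(sprintf("  L     = %g cm, S = %g cm^2\n", x$L, x$S))
  cat(sprintf("  Fin   = vFin/v = %g mM\n", food_inflow_conc(x)))
  invisible(x)
}

#' Inflowing food concentration
#'
#' The concentration of food entering at `x = 0`, `Fin = vFin / v` (mM).
#'
#' @param params A [gut_parameters()] object.
#' @return Numeric scalar (mM).
#' @export
food_inflow_conc <- function(params) {
  stopifnot(inherits(params, "gut_params"))
  params$vFin / params$v
}

#' Uniform cell-centred spatial grid
#'
#' Discretises the gut segment `[0, L]` into `n_cells` equal cells; field
#' values live at cell centres and fluxes at cell faces.
#'
#' @param params A [gut_parameters()] object (supplies `L`).
#' @param n_cells Number of cells (at least 10).  The default, 100 cells
#'   per cm, resolves the steepest bacterial fronts arising at the
#'   parameters studied here (front width ~ D/v).
#' @return An object of class `gut_grid` with fields `n_cells`, `dx`,
#'   `cell_centers`, `L`.
#' @export
build_grid <- function(params, n_cells = round(100 * params$L)) {
  stopifnot(inherits(params, "gut_params"))
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 10)
    stop("n_cells must be at least 10 for a meaningful resolution",
         call. = FALSE)
  dx <- params$L / n_cells
  g <- list(n_cells = n_cells, dx = dx,
            cell_centers = (seq_len(n_cells) - 0.5) * dx,
            L = params$L)
  class(g) <- "gut_grid"
  g
}

#' @export
print.gut_grid <- function(x, ...) {
  cat(sprintf("Cell-centred grid: %d cells, dx = %g cm, covering [0, %g]\n",
              x$n_cells, x$dx, x$L))
  invisible(x)
}

#' Dimensionless groups of the stationary-state problem
#'
#' Three dimensionless parameters fully describe the shape of the
#' stationary state (after rescaling x by L, concentrations by `Fin` and
#' `alpha * Fin`): the Peclet number `vL/D` (advection vs diffusion over
#' the segment), the growth number `rL/v` (divisions per transit), and the
#' saturation ratio `k/Fin` (how far below Monod saturation the inflowing
#' food sits).  Both washout limits are single-parameter thresholds in
#' this basis.
#'
#' @param params A [gut_parameters()] object.
#' @return Object of class `gut_dimensionless` with fields `peclet`,
#'   `growth_number`, `saturation`.
#' @export
nondimensionalize <- function(params) {
  stopifnot(inherits(params, "gut_params"))
  out <- list(peclet = params$v * params$L / params$D,
              growth_number = params$r * params$L / params$v,
              saturation = params$k / food_inflow_conc(params))
  class(out) <- "gut_dimensionless"
  out
}

#' @export
print.gut_dimensionless <- function(x, ...) {
  cat(sprintf("Peclet vL/D = %g, growth rL/v = %g, saturation k/Fin = %g\n",
              x$peclet, x$growth_number, x$saturation))
  invisible(x)
}

#' Read a parameter/numerics configuration file
#'
#' Reads a flat YAML or JSON map.  Physical keys (`v, D, r, k, vFin,
#' alpha, L, S`) are validated through [make_parameters()]; the remaining
#' recognised numerics keys (`n_cells`, `t_max`, `tol`, `seed`) are
#' returned alongside.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param overrides Named list applied on top of the file contents
#'   (CLI-style overrides).
#' @return List with elements `params` (class `gut_params`) and `numerics`
#'   (named list, possibly empty).
#' @export
read_config <- function(path, overrides = list()) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, call. = FALSE))
  cfg <- utils::modifyList(as.list(cfg), overrides)
  phys_keys <- c("v", "D", "r", "k", "vFin", "alpha", "L", "S")
  num_keys <- c("n_cells", "t_max", "tol", "seed")
  extra <- setdiff(names(cfg), c(phys_keys, num_keys))
  if (length(extra) > 0)
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  params <- make_parameters(cfg[intersect(phys_keys, names(cfg))])
  list(params = params, numerics = cfg[intersect(num_keys, names(cfg))])
}
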