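#' Write a field state or steady profile to a tidy table
#'
#' One row per cell with columns `x, F, B, M` (and `rho` for steady
#' states); comma- or tab-separated by file extension, with unit-carrying
#' header comments.
#'
#' @param x A [field_state()] or `gut_steady` object.
#' @param path Output path (`.csv` or `.tsv`).
#' @param grid Grid (required for a bare field state).
#' @param params Parameters (used to add the `rho` column; optional).
#' @return The path, invisibly.
#' @export
write_profile <- function(x, path, grid = NULL, params = NULL) {
  if (inherits(x, "gut_steady")) {
    if (is.null(grid)) grid <- x$grid
    if (is.null(params)) params <- x$params
    x <- x$state
  }
  stopifnot(inherits(x, "gut_field_state"), inherits(grid, "gut_grid"))
  df <- data.frame(x = grid$cell_centers, F = x$F, B = x$B, M = x$M)
  if (!is.null(params)) df$rho <- reproduction_rate(x$F, params)
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# gut concentration profile",
               "# x: cm; F: mM; B, M: bacteria/cm^3; rho: 1/h",
               sprintf("# t = %g h", x$t)), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a concentration profile from a tidy table
#'
#' Expects header columns `x, F, B` and optionally `M` (defaulting to
#' zero), with `x` strictly increasing on a uniform grid; `#` lines are
#' treated as comments.  Malformed input is rejected with the offending
#' row named.
#'
#' @param path `.csv` or `.tsv` file.
#' @return A [field_state()]; the inferred grid is attached as attribute
#'   `grid` (class `gut_grid`, with `L = n * dx` inferred from spacing).
#' @export
read_profile <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", check.names = TRUE)
  need <- c("x", "F", "B")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("profile is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!("M" %in% names(df))) df$M <- 0
  for (col in c("x", "F", "B", "M")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0)
      stop(sprintf("non-numeric value in column '%s' at data row %d",
                   col, bad[1]), call. = FALSE)
  }
  for (col in c("F", "B", "M")) {
    bad <- which(df[[col]] < 0)
    if (length(bad) > 0)
      stop(sprintf("negative concentration in column '%s' at data row %d",
                   col, bad[1]), call. = FALSE)
  }
  dxs <- diff(df$x)
  if (any(dxs <= 0))
    stop(sprintf("x must be strictly increasing (violated at data row %d)",
                 which(dxs <= 0)[1] + 1), call. = FALSE)
  dx <- mean(dxs)
  if (max(abs(dxs - dx)) > 1e-6 * dx)
    stop(sprintf("non-uniform grid spacing at data row %d",
                 which.max(abs(dxs - dx)) + 1), call. = FALSE)
  n <- nrow(df)
  state <- field_state(F = df$F, B = df$B, M = df$M)
  grid <- list(n_cells = n, dx = dx, cell_centers = df$x, L = n * dx)
  class(grid) <- "gut_grid"
  attr(state, "grid") <- grid
  state
}

#' Write a run manifest
#'
#' Records, as JSON, everything needed to reproduce a run: the resolved
#' parameters and numerics, the package version, a timestamp and the
#' output files with checksums.
#'
#' @param path Manifest path (`.json`).
#' @param command Name of the command or pipeline.
#' @param params A [gut_parameters()] object.
#' @param numerics Named list of numerical settings (grid, tolerances,
#'   seed, ...).
#' @param outputs Character vector of output file paths.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(path, command, params, numerics = list(),
                               outputs = character()) {
  manifest <- list(
    command = command,
    parameters = unclass(params),
    numerics = numerics,
    package_version = as.character(utils::packageVersion("gutfix")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(outputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Data pipelines behind the headline figures
#'
#' Regenerates the data underlying the main analyses as tidy data frames
#' (and optionally CSV files plus a manifest):
#' \describe{
#'   \item{`steady_profiles`}{Steady `F`, `B`, `rho` along the gut at the
#'     reference strongly spatial parameters.}
#'   \item{`phase_diagram`}{Spatial-dependence metric over a (v, D) grid
#'     with the analytic washout thresholds.}
#'   \item{`fixation_vs_position`}{`C(xM)`, `R(xM)` and their product.}
#'   \item{`fixation_vs_population`}{Overall fixation vs `NT` as `v` is
#'     swept at fixed `D` and fixed food inflow.}
#'   \item{`fixation_vs_active`}{Fixation vs `NA` across food inflow
#'     rates, restricted to strongly spatial profiles
#'     (`spatial dependence > 0.9`).}
#' }
#'
#' @param name Pipeline name (see above).
#' @param params Base parameters (defaults to [gut_parameters()]).
#' @param out_dir Optional directory; when given, a CSV and a JSON
#'   manifest are written there.
#' @param n_cells Grid resolution.
#' @param NM Introduced mutant count for the fixation pipelines.
#' @param ... Pipeline-specific settings: `v_values`, `D_values`
#'   (`phase_diagram`, `fixation_vs_population`), `vFin_values` and
#'   `v_ranges` (`fixation_vs_active`), `threshold`.
#' @return The data frame (invisibly when written to disk).
#' @export
figure_pipeline <- function(name = c("steady_profiles", "phase_diagram",
                                     "fixation_vs_position",
                                     "fixation_vs_population",
                                     "fixation_vs_active"),
                            params = gut_parameters(), out_dir = NULL,
                            n_cells = round(100 * params$L), NM = 1, ...) {
  name <- match.arg(name)
  dots <- list(...)
  df <- switch(name,
    steady_profiles = {
      grid <- build_grid(params, n_cells)
      st <- solve_steady_state(params, grid)
      data.frame(x = grid$cell_centers, F = st$state$F, B = st$state$B,
                 M = st$state$M,
                 rho = reproduction_rate(st$state$F, params))
    },
    phase_diagram = {
      v_values <- dots$v_values %||%
        exp(seq(log(0.05), log(2.4), length.out = 8))
      D_values <- dots$D_values %||%
        exp(seq(log(0.02), log(20), length.out = 8))
      rows <- list()
      for (D in D_values) for (v in v_values) {
        p <- params; p$v <- v; p$D <- D
        th <- washout_thresholds(p)
        analytic <- classify_regime(p, steady = NULL,
                                    threshold = Inf)$label
        dep <- NA_real_
        if (!startsWith(analytic, "washout")) {
          st <- solve_steady_state(p, build_grid(p, n_cells))
          dep <- if (st$washout) NA_real_ else spatial_dependence(st, p)
        }
        rows[[length(rows) + 1]] <-
          data.frame(v = v, D = D, spatial_dependence = dep,
                     regime = analytic, d_crit = th$d_crit,
                     v_crit = th$v_crit)
      }
      do.call(rbind, rows)
    },
    fixation_vs_position = {
      rep_ <- fixation_report(params, NM = NM,
                              grid = build_grid(params, n_cells))
      data.frame(xM = rep_$grid$cell_centers, C = as.numeric(rep_$ratio_curve),
                 R = rep_$R_curve,
                 RC = rep_$R_curve * as.numeric(rep_$ratio_curve))
    },
    fixation_vs_population = {
      D_values <- dots$D_values %||% c(0.02, 0.2, 2, 20)
      v_values <- dots$v_values %||%
        exp(seq(log(0.02), log(2.4), length.out = 10))
      sweep_fixation_vs_population(params, D_values, v_values, NM = NM,
                                   n_cells = n_cells)
    },
    fixation_vs_active = {
      vFin_values <- dots$vFin_values %||% c(0.1, 1, 10)
      v_ranges <- dots$v_ranges %||% list(
        seq(0.135, 0.171, length.out = 6),
        seq(0.15, 0.185, length.out = 6),
        seq(0.15, 0.186, length.out = 6))
      threshold <- dots$threshold %||% 0.9
      rows <- list()
      for (j in seq_along(vFin_values)) {
        p <- params
        p$vFin <- vFin_values[j]
        p$D <- dots$D %||% 0.02
        sw <- sweep_fixation_vs_population(p, p$D, v_ranges[[j]],
                                           NM = NM, n_cells = n_cells)
        sw$vFin <- vFin_values[j]
        rows[[length(rows) + 1]] <- sw
      }
      out <- do.call(rbind, rows)
      out[!is.na(out$spatial_dependence) &
            out$spatial_dependence > threshold, ]
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, csv, row.names = FALSE)
    write_run_manifest(file.path(out_dir, paste0(name, "_manifest.json")),
                       command = paste0("figure_pipeline:", name),
                       params = params,
                       numerics = c(list(n_cells = n_cells, NM = NM), dots),
                       outputs = csv)
    return(invisible(df))
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
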