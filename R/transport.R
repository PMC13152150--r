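# Explicit finite-difference diffusion-reaction transport on a rectangular
# anode-compartment cross-section. Cell-centered 5-point Laplacian, no-flux
# (reflecting) boundaries, forward Euler with an enforced stability bound.
# The biofilm is a static enhanced-reaction band adjacent to the anode
# boundary (x = 0): glucose is consumed at first order there, producing H+
# and CO2 in the 24:6 stoichiometric ratio of glucose oxidation.

#' Rectangular 2-D grid
#'
#' Cell-centered grid; field matrices are indexed `[i, j]` with row `i`
#' running along x (anode at x = 0) and column `j` along y.
#'
#' @param nx,ny Cell counts (at least 4 each).
#' @param Lx,Ly Domain size, m.
#' @return An object of class `grid2d` with cell sizes `dx`, `dy` and
#'   cell-center coordinates `x`, `y`.
#' @export
grid2d <- function(nx = 50, ny = 50, Lx = 0.01, Ly = 0.01) {
  if (nx < 4 || ny < 4) stop("'nx' and 'ny' must be >= 4", call. = FALSE)
  if (Lx <= 0 || Ly <= 0) stop("'Lx' and 'Ly' must be positive", call. = FALSE)
  dx <- Lx / nx; dy <- Ly / ny
  structure(list(nx = nx, ny = ny, Lx = Lx, Ly = Ly, dx = dx, dy = dy,
                 x = (seq_len(nx) - 0.5) * dx, y = (seq_len(ny) - 0.5) * dy),
            class = "grid2d")
}

#' Build the simulation domain with its static biofilm band
#'
#' The biofilm occupies `ceil(thickness / dx)` whole cell columns adjacent
#' to the anode boundary at x = 0.
#'
#' @param grid A [grid2d()].
#' @param biofilm_thickness Band thickness, m; must be positive and below
#'   `Lx / 2`.
#' @return An object of class `transport_domain` with a logical `mask`
#'   (nx x ny) marking biofilm cells and `n_band` columns.
#' @export
build_domain <- function(grid, biofilm_thickness = 1e-3) {
  stopifnot(inherits(grid, "grid2d"))
  if (biofilm_thickness >= grid$Lx / 2)
    stop("'biofilm_thickness' must be below Lx/2", call. = FALSE)
  n_band <- ceiling(biofilm_thickness / grid$dx)
  if (n_band < 1)
    stop("'biofilm_thickness' rounds to zero cells (dx = ", grid$dx, " m)",
         call. = FALSE)
  mask <- matrix(FALSE, grid$nx, grid$ny)
  mask[seq_len(n_band), ] <- TRUE
  structure(list(grid = grid, mask = mask, n_band = n_band,
                 biofilm_thickness = biofilm_thickness),
            class = "transport_domain")
}

#' Transport parameters
#'
#' Aqueous diffusivities (literature-typical 25-30 C values, editable),
#' first-order glucose consumption rate inside the biofilm band, product
#' yields per mole glucose consumed, and an optional O2 influx on the
#' cathode-side boundary (x = Lx).
#'
#' @param D Named diffusivities, m^2/s, for `glucose`, `hplus`, `co2`, `o2`.
#' @param k_glu First-order glucose consumption rate in the biofilm, 1/s.
#' @param yield_h,yield_co2 mol H+ / mol CO2 produced per mol glucose
#'   consumed (defaults 24 and 6, the glucose-oxidation stoichiometry).
#' @param o2_influx O2 influx across the cathode-side boundary,
#'   mol/(m^2 s); default 0.
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(D = c(glucose = 6.7e-10, hplus = 9.3e-9,
                                   co2 = 1.9e-9, o2 = 2.1e-9),
                             k_glu = 1e-3, yield_h = 24, yield_co2 = 6,
                             o2_influx = 0) {
  need <- c("glucose", "hplus", "co2", "o2")
  if (!all(need %in% names(D)))
    stop("'D' must name ", paste(need, collapse = ", "), call. = FALSE)
  if (any(D <= 0)) stop("diffusivities must be positive", call. = FALSE)
  if (k_glu < 0) stop("'k_glu' must be >= 0", call. = FALSE)
  if (yield_h < 0 || yield_co2 < 0) stop("yields must be >= 0", call. = FALSE)
  structure(list(D = D[need], k_glu = k_glu, yield_h = yield_h,
                 yield_co2 = yield_co2, o2_influx = o2_influx),
            class = "transport_params")
}

#' Explicit-scheme stability bound on the time step
#'
#' `dt <= dx^2 dy^2 / (2 Dmax (dx^2 + dy^2))` for the 5-point forward-Euler
#' stencil.
#'
#' @param grid A [grid2d()].
#' @param params A [transport_params()].
#' @return Maximum stable time step, s.
#' @export
stability_dt <- function(grid, params) {
  dx2 <- grid$dx^2; dy2 <- grid$dy^2
  dx2 * dy2 / (2 * max(params$D) * (dx2 + dy2))
}

#' Uniform initial fields
#'
#' @param domain A [build_domain()] result.
#' @param glucose,hplus,co2,o2 Uniform initial concentrations, mol/m^3.
#' @return Named list of nx x ny matrices.
#' @export
initial_fields <- function(domain, glucose = 1, hplus = 0, co2 = 0, o2 = 0) {
  g <- domain$grid
  lapply(c(glucose = glucose, hplus = hplus, co2 = co2, o2 = o2),
         function(v) matrix(v, g$nx, g$ny))
}

# 5-point Laplacian with reflecting (no-flux) boundaries
laplacian_noflux <- function(c, dx, dy) {
  nx <- nrow(c); ny <- ncol(c)
  up <- c[c(1L, seq_len(nx - 1L)), , drop = FALSE]
  dn <- c[c(seq_len(nx)[-1L], nx), , drop = FALSE]
  lf <- c[, c(1L, seq_len(ny - 1L)), drop = FALSE]
  rt <- c[, c(seq_len(ny)[-1L], ny), drop = FALSE]
  (up + dn - 2 * c) / dx^2 + (lf + rt - 2 * c) / dy^2
}

#' Advance the transport state by one explicit time step
#'
#' Forward-Euler update of all four species with the biofilm reaction terms;
#' errors if `dt` exceeds the stability bound. Negative concentrations are
#' clipped at zero with a warning. The per-cell cumulative glucose
#' consumption (mol/m^3) is accumulated in `consumed`.
#'
#' @param state List with elements `fields` (see [initial_fields()]),
#'   `consumed` (matrix) and `t` (s).
#' @param domain A [build_domain()] result.
#' @param params A [transport_params()].
#' @param dt Time step, s.
#' @return Updated state list.
#' @export
step_fields <- function(state, domain, params, dt) {
  g <- domain$grid
  bound <- stability_dt(g, params)
  if (dt > bound * (1 + 1e-12))
    stop("dt = ", dt, " s violates the explicit stability bound ", bound,
         " s", call. = FALSE)
  f <- state$fields
  rate <- params$k_glu * f$glucose * domain$mask   # mol/(m^3 s), band only
  new <- list(
    glucose = f$glucose +
      dt * (params$D[["glucose"]] * laplacian_noflux(f$glucose, g$dx, g$dy) -
              rate),
    hplus = f$hplus +
      dt * (params$D[["hplus"]] * laplacian_noflux(f$hplus, g$dx, g$dy) +
              params$yield_h * rate),
    co2 = f$co2 +
      dt * (params$D[["co2"]] * laplacian_noflux(f$co2, g$dx, g$dy) +
              params$yield_co2 * rate),
    o2 = f$o2 + dt * params$D[["o2"]] * laplacian_noflux(f$o2, g$dx, g$dy))
  if (params$o2_influx > 0)
    new$o2[g$nx, ] <- new$o2[g$nx, ] + dt * params$o2_influx / g$dx
  clipped <- FALSE
  for (sp in names(new)) {
    if (any(new[[sp]] < 0)) {
      clipped <- TRUE
      new[[sp]][new[[sp]] < 0] <- 0
    }
  }
  if (clipped)
    warning("negative concentrations clipped at 0", call. = FALSE)
  list(fields = new, consumed = state$consumed + dt * rate,
       t = state$t + dt)
}

#' Simulate diffusion-reaction transport over the anode domain
#'
#' Integrates the explicit scheme to `t_end`, recording full fields at the
#' requested output times (the step lands exactly on each output time).
#'
#' @param domain A [build_domain()] result.
#' @param params A [transport_params()].
#' @param init Initial fields (default [initial_fields()] with 1 mol/m^3
#'   glucose).
#' @param t_end Final time, s.
#' @param out_times Output times, s; default 25 equally spaced points
#'   including 0 and `t_end`.
#' @param safety Fraction of the stability bound used as the base step.
#' @return An object of class `field_series`: `times`, `snapshots` (list per
#'   time of per-species matrices), `averages` (data frame of domain means),
#'   `consumed` (final cumulative consumption matrix), plus the domain and
#'   parameters.
#' @export
simulate_transport <- function(domain, params, init = NULL, t_end = 7200,
                               out_times = NULL, safety = 0.9) {
  stopifnot(inherits(domain, "transport_domain"),
            inherits(params, "transport_params"))
  if (is.null(init)) init <- initial_fields(domain)
  if (is.null(out_times)) out_times <- seq(0, t_end, length.out = 25)
  out_times <- sort(unique(c(0, out_times)))
  if (max(out_times) > t_end)
    stop("'out_times' must not exceed 't_end'", call. = FALSE)
  dt0 <- safety * stability_dt(domain$grid, params)
  state <- list(fields = init,
                consumed = matrix(0, domain$grid$nx, domain$grid$ny),
                t = 0)
  snapshots <- vector("list", length(out_times))
  names(snapshots) <- format(out_times)
  rec <- function(k, s) snapshots[[k]] <<- s$fields
  k <- 1L
  if (out_times[1] == 0) { rec(1L, state); k <- 2L }
  while (k <= length(out_times)) {
    target <- out_times[k]
    while (state$t < target - 1e-9) {
      dt <- min(dt0, target - state$t)
      state <- step_fields(state, domain, params, dt)
    }
    rec(k, state)
    k <- k + 1L
  }
  avg <- data.frame(
    t_s = out_times,
    glucose = vapply(snapshots, function(s) mean(s$glucose), numeric(1)),
    hplus = vapply(snapshots, function(s) mean(s$hplus), numeric(1)),
    co2 = vapply(snapshots, function(s) mean(s$co2), numeric(1)),
    o2 = vapply(snapshots, function(s) mean(s$o2), numeric(1)),
    row.names = NULL)
  structure(list(times = out_times, snapshots = snapshots, averages = avg,
                 consumed = state$consumed, domain = domain, params = params),
            class = "field_series")
}

#' Domain-average concentration time series for one species
#'
#' @param series A [simulate_transport()] result.
#' @param species One of `"glucose"`, `"hplus"`, `"co2"`, `"o2"`.
#' @return Data frame with columns `t_s` and `mean_mol_per_m3`.
#' @export
species_timeseries <- function(series, species) {
  stopifnot(inherits(series, "field_series"))
  if (!species %in% c("glucose", "hplus", "co2", "o2"))
    stop("unknown species '", species, "'", call. = FALSE)
  data.frame(t_s = series$averages$t_s,
             mean_mol_per_m3 = series$averages[[species]])
}

#' Biofilm-activity profile across the compartment
#'
#' The biofilm-activity proxy is the local cumulative glucose consumption
#' (mol/m^3) at final time, averaged along the anode-parallel (y) axis,
#' giving a 1-D profile versus distance from the anode boundary.
#'
#' @param series A [simulate_transport()] result.
#' @return Data frame with columns `x_m` and `consumed_mol_per_m3`.
#' @export
biofilm_profile <- function(series) {
  stopifnot(inherits(series, "field_series"))
  data.frame(x_m = series$domain$grid$x,
             consumed_mol_per_m3 = rowMeans(series$consumed))
}

#' Write a field snapshot to CSV
#'
#' Cell-centered values with x, y coordinate columns (anode at x = 0).
#' @param series A [simulate_transport()] result.
#' @param species Species name.
#' @param time Output time to write (must be one of `series$times`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(series, species, time, path) {
  k <- match(TRUE, abs(series$times - time) < 1e-9)
  if (is.na(k)) stop("time ", time, " s not among output times", call. = FALSE)
  g <- series$domain$grid
  m <- series$snapshots[[k]][[species]]
  df <- data.frame(x_m = rep(g$x, times = g$ny),
                   y_m = rep(g$y, each = g$nx),
                   conc_mol_per_m3 = as.vector(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# species=%s t_s=%g cell-centered, anode at x=0",
                     species, series$times[k]), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
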