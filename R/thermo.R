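# Stoichiometric flowsheet: specified-conversion anode reactor, proton-
# selective separator, cathode reactor. Electrons are carried as an explicit
# zero-mass bookkeeping species so charge closure is testable; they are
# routed through the external circuit, not the separator.

mfc_species <- c("glucose", "water", "co2", "proton", "oxygen", "electron")

#' Species table for the glucose MFC flowsheet
#'
#' Elemental composition (C, H, O) and charge of the six species tracked by
#' the flowsheet. The electron is a mass-free bookkeeping species with
#' charge -1.
#'
#' @return Data frame with columns `species`, `C`, `H`, `O`, `charge`.
#' @export
species_table <- function() {
  data.frame(
    species = mfc_species,
    C = c(6, 0, 1, 0, 0, 0),
    H = c(12, 2, 0, 1, 0, 0),
    O = c(6, 1, 2, 0, 2, 0),
    charge = c(0, 0, 0, 1, 0, -1),
    stringsAsFactors = FALSE)
}

#' Construct a validated reaction
#'
#' Signed stoichiometric coefficients (negative = consumed). Element (C, H,
#' O) and charge balances are enforced at construction.
#'
#' @param stoich Named numeric vector of coefficients over the species in
#'   [species_table()].
#' @param n_electrons Electrons transferred per formula unit.
#' @return An object of class `mfc_reaction`.
#' @export
reaction <- function(stoich, n_electrons = 0) {
  bad <- setdiff(names(stoich), mfc_species)
  if (length(bad))
    stop("unknown species: ", paste(bad, collapse = ", "), call. = FALSE)
  full <- stats::setNames(numeric(length(mfc_species)), mfc_species)
  full[names(stoich)] <- stoich
  tab <- species_table()
  for (el in c("C", "H", "O")) {
    res <- sum(full * tab[[el]])
    if (abs(res) > 1e-12)
      stop("element balance violated for ", el, " (residual ", res, ")",
           call. = FALSE)
  }
  qres <- sum(full * tab$charge)
  if (abs(qres) > 1e-12)
    stop("charge balance violated (residual ", qres, ")", call. = FALSE)
  structure(list(stoich = full, n_electrons = n_electrons),
            class = "mfc_reaction")
}

#' Anode half-reaction: glucose oxidation
#'
#' C6H12O6 + 6 H2O -> 6 CO2 + 24 H+ + 24 e-
#' @return An `mfc_reaction` with 24 electrons per glucose.
#' @export
anode_reaction <- function() {
  reaction(c(glucose = -1, water = -6, co2 = 6, proton = 24, electron = 24),
           n_electrons = 24)
}

#' Cathode half-reaction: oxygen reduction
#'
#' O2 + 4 H+ + 4 e- -> 2 H2O
#' @return An `mfc_reaction` with 4 electrons per O2.
#' @export
cathode_reaction <- function() {
  reaction(c(oxygen = -1, proton = -4, electron = -4, water = 2),
           n_electrons = 4)
}

#' Overall cell reaction: aerobic glucose oxidation
#'
#' C6H12O6 + 6 O2 -> 6 CO2 + 6 H2O; equals the anode half-reaction plus six
#' times the cathode half-reaction with protons and electrons cancelling.
#' @return An `mfc_reaction`.
#' @export
overall_reaction <- function() {
  reaction(c(glucose = -1, oxygen = -6, co2 = 6, water = 6), n_electrons = 24)
}

#' Construct a process stream
#'
#' @param flows Named molar flows, mol/h, all non-negative.
#' @param T Temperature, K.
#' @param P Pressure, bar.
#' @return An object of class `mfc_stream`.
#' @export
stream <- function(flows = numeric(0), T = 303.15, P = 1) {
  bad <- setdiff(names(flows), mfc_species)
  if (length(bad))
    stop("unknown species: ", paste(bad, collapse = ", "), call. = FALSE)
  full <- stats::setNames(numeric(length(mfc_species)), mfc_species)
  full[names(flows)] <- flows
  if (any(full < 0)) stop("stream flows must be non-negative", call. = FALSE)
  structure(list(flows = full, T = T, P = P), class = "mfc_stream")
}

#' @export
print.mfc_stream <- function(x, ...) {
  cat(sprintf("<mfc_stream> T = %g K, P = %g bar\n", x$T, x$P))
  nz <- x$flows[x$flows != 0]
  if (length(nz)) print(round(nz, 9)) else cat("  (empty)\n")
  invisible(x)
}

#' Element and charge totals of a stream
#'
#' @param s An `mfc_stream`.
#' @return Named vector: total C, H, O (mol atoms/h) and net charge (mol/h).
#' @export
element_totals <- function(s) {
  stopifnot(inherits(s, "mfc_stream"))
  tab <- species_table()
  c(C = sum(s$flows * tab$C), H = sum(s$flows * tab$H),
    O = sum(s$flows * tab$O), charge = sum(s$flows * tab$charge))
}

#' Specified-conversion stoichiometric reactor
#'
#' Applies `rxn` to `feed` at a specified conversion of the limiting
#' reagent: extent = conversion x min over reactants of
#' (feed flow / |coefficient|). Element totals are conserved exactly.
#'
#' @param feed An `mfc_stream`.
#' @param rxn An `mfc_reaction`.
#' @param conversion Fraction of the limiting reagent reacted, in [0, 1].
#' @return Outlet `mfc_stream`.
#' @export
react_stream <- function(feed, rxn, conversion) {
  stopifnot(inherits(feed, "mfc_stream"), inherits(rxn, "mfc_reaction"))
  if (!is.finite(conversion) || conversion < 0 || conversion > 1)
    stop("'conversion' must lie in [0, 1]", call. = FALSE)
  reactants <- names(rxn$stoich)[rxn$stoich < 0]
  ratios <- feed$flows[reactants] / abs(rxn$stoich[reactants])
  extent <- conversion * min(ratios)
  out <- feed$flows + extent * rxn$stoich
  neg <- names(out)[out < -1e-12]
  if (length(neg))
    stop("reaction extent drives negative flow for: ",
         paste(neg, collapse = ", "), call. = FALSE)
  res <- stream(pmax(out, 0), T = feed$T, P = feed$P)
  attr(res, "extent") <- extent
  res
}

#' Separator specification
#'
#' Per-species permeation fractions in [0, 1]; the permeate carries
#' `fraction * inlet`, the retentate the remainder. The default emulates a
#' proton exchange membrane: all protons permeate, 2% water carry-over,
#' nothing else crosses.
#'
#' @param permeation Named fractions over species.
#' @return An object of class `separator_spec`.
#' @export
separator_spec <- function(permeation = c(proton = 1, water = 0.02)) {
  bad <- setdiff(names(permeation), mfc_species)
  if (length(bad))
    stop("unknown species: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(permeation < 0 | permeation > 1))
    stop("permeation fractions must lie in [0, 1]", call. = FALSE)
  full <- stats::setNames(numeric(length(mfc_species)), mfc_species)
  full[names(permeation)] <- permeation
  structure(list(permeation = full), class = "separator_spec")
}

#' Split a stream across a separator
#'
#' @param s Inlet `mfc_stream`.
#' @param spec A [separator_spec()].
#' @return List with elements `permeate` and `retentate`; per species the
#'   two sum exactly to the inlet.
#' @export
separate <- function(s, spec = separator_spec()) {
  stopifnot(inherits(s, "mfc_stream"), inherits(spec, "separator_spec"))
  perm <- s$flows * spec$permeation
  ret <- s$flows - perm
  list(permeate = stream(perm, T = s$T, P = s$P),
       retentate = stream(ret, T = s$T, P = s$P))
}

#' Merge streams (species-wise flow addition)
#' @param ... `mfc_stream` objects; T and P taken from the first.
#' @return Combined `mfc_stream`.
#' @export
merge_streams <- function(...) {
  ss <- list(...)
  stopifnot(all(vapply(ss, inherits, logical(1), "mfc_stream")))
  flows <- Reduce(`+`, lapply(ss, `[[`, "flows"))
  stream(flows, T = ss[[1]]$T, P = ss[[1]]$P)
}

#' Cathode reactor stage
#'
#' Combines the separator permeate with an oxygen feed (and the external-
#' circuit electron stream) and applies the cathode half-reaction at the
#' specified conversion of the limiting reagent.
#'
#' @param permeate Proton-rich `mfc_stream` from the separator.
#' @param o2_feed Oxygen `mfc_stream` (may also carry electrons from the
#'   external circuit).
#' @param conversion Fraction of the limiting reagent reacted.
#' @return Outlet `mfc_stream`.
#' @export
cathode_stage <- function(permeate, o2_feed, conversion) {
  react_stream(merge_streams(permeate, o2_feed), cathode_reaction(),
               conversion)
}

#' Reaction enthalpy from formation enthalpies
#'
#' Sum of coefficient x standard formation enthalpy; negative = exothermic.
#' The electron's formation enthalpy is defined as 0.
#'
#' @param rxn An `mfc_reaction`.
#' @param dHf Named formation enthalpies, kJ/mol; defaults to the shipped
#'   25 C reference table.
#' @return Reaction enthalpy, kJ/mol of formula turnover.
#' @export
reaction_enthalpy <- function(rxn, dHf = load_formation_enthalpies()) {
  stopifnot(inherits(rxn, "mfc_reaction"))
  active <- names(rxn$stoich)[rxn$stoich != 0]
  missing <- setdiff(active, names(dHf))
  if (length(missing))
    stop("formation enthalpy missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sum(rxn$stoich[active] * dHf[active])
}

#' Load the shipped standard formation-enthalpy table
#'
#' 25 C reference values, kJ/mol (editable CSV under `extdata/`).
#' @param path CSV path; defaults to the packaged file.
#' @return Named numeric vector, kJ/mol.
#' @export
load_formation_enthalpies <- function(
    path = system.file("extdata", "formation_enthalpies.csv",
                       package = "mfcsim")) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(tab$dHf_kJ_per_mol, tab$species)
}

#' Theoretical electron flow and equivalent current
#'
#' Coulombic bound implied by glucose stoichiometry: 24 mol electrons per
#' mol glucose reacted; current = electron flow x F / 3600.
#'
#' @param feed An `mfc_stream`.
#' @param conversion Anode conversion of the limiting reagent.
#' @param consts A [physical_constants()] object.
#' @return List with `electron_mol_per_h` and `current_A`.
#' @export
max_electron_flow <- function(feed, conversion,
                              consts = physical_constants()) {
  out <- react_stream(feed, anode_reaction(), conversion)
  e_flow <- 24 * attr(out, "extent")
  list(electron_mol_per_h = e_flow, current_A = e_flow * consts$F / 3600)
}

#' Run the anode - separator - cathode flowsheet chain
#'
#' Feed enters the specified-conversion anode reactor; electrons produced
#' there are diverted to the external circuit; the remaining effluent is
#' split across the proton-selective separator; the permeate, circuit
#' electrons and an oxygen feed enter the cathode reactor. Element totals
#' are conserved end-to-end.
#'
#' @param feed Anode feed `mfc_stream` (glucose + water by default).
#' @param anode_conversion,cathode_conversion Specified conversions.
#' @param separator A [separator_spec()].
#' @param o2_feed Oxygen feed `mfc_stream`; `NULL` sizes it
#'   stoichiometrically (extent x 6 mol O2 per mol glucose reacted).
#' @param dHf Formation-enthalpy table for the energy summary.
#' @param consts A [physical_constants()] object.
#' @return List of class `mfc_flowsheet`: the five streams, the circuit
#'   electron flow/current, element residuals (in - out over all terminal
#'   streams), and enthalpy per mole glucose reacted.
#' @export
run_flowsheet <- function(feed = stream(c(glucose = 1, water = 50)),
                          anode_conversion = 0.99, cathode_conversion = 0.99,
                          separator = separator_spec(), o2_feed = NULL,
                          dHf = load_formation_enthalpies(),
                          consts = physical_constants()) {
  anode_out <- react_stream(feed, anode_reaction(), anode_conversion)
  extent <- attr(anode_out, "extent")
  # electrons leave through the external circuit, not the separator
  circuit <- stream(c(electron = anode_out$flows[["electron"]]),
                    T = anode_out$T, P = anode_out$P)
  anode_eff <- anode_out
  anode_eff$flows[["electron"]] <- 0
  sep <- separate(anode_eff, separator)
  if (is.null(o2_feed))
    o2_feed <- stream(c(oxygen = 6 * extent), T = feed$T, P = feed$P)
  cath_in <- merge_streams(sep$permeate, circuit)
  cathode_out <- cathode_stage(cath_in, o2_feed, cathode_conversion)
  tot_in <- element_totals(feed) + element_totals(o2_feed)
  tot_out <- element_totals(sep$retentate) + element_totals(cathode_out)
  dH <- reaction_enthalpy(overall_reaction(), dHf)
  structure(list(
    feed = feed, anode_out = anode_out, permeate = sep$permeate,
    retentate = sep$retentate, cathode_out = cathode_out,
    o2_feed = o2_feed,
    electron_mol_per_h = circuit$flows[["electron"]],
    current_A = circuit$flows[["electron"]] * consts$F / 3600,
    glucose_reacted_mol_per_h = extent,
    element_residuals = tot_in - tot_out,
    enthalpy_kJ_per_mol_glucose = dH),
    class = "mfc_flowsheet")
}

#' Write a stream to CSV
#'
#' Columns `species`, `mol_per_h`; T and P recorded in a comment header.
#' @param s An `mfc_stream`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(s, path) {
  stopifnot(inherits(s, "mfc_stream"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# T_K=%g P_bar=%g", s$T, s$P), con)
  utils::write.csv(data.frame(species = names(s$flows),
                              mol_per_h = unname(s$flows)),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
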