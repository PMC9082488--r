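#' Metabolite catalogs for edited difference spectra
#'
#' The catalog is the ground-truth parametric model of how each metabolite
#' responds to the two editing dimensions. Each entry carries a line table with
#' a chemical-shift offset and *two* (signed amplitude, phase) states per line
#' -- the value under edit-ON and under edit-OFF of the editing dimension the
#' line responds to (`edit_dim` of `"gaba"`, `"gsh"` or `"none"`). Editing
#' physics is thereby encoded rather than simulated: e.g. the GSH 2.95-ppm
#' lines flip sign between GSH-ON and GSH-OFF so they survive the GSH-targeted
#' combination, while unedited singlets (NAA, tCr, tCho) are identical across
#' sub-experiments and cancel exactly in any difference.
#'
#' The two TE presets differ in the co-edited aspartyl multiplet at ~2.6 ppm:
#' at TE 80 ms its lines are strongly mixed-phase (the quantification hazard
#' for simple Gaussian peak fitting), at TE 120 ms they are near-absorptive.
#' The preset line tables are versioned fixtures chosen to reproduce that
#' qualitative contrast; they are not a spin-physics simulation.
#'
#' @param te_preset `"HERMES80"` or `"MEGA120"`.
#' @return An object of class `metabolite_catalog` with fields `entries`
#'   (named list) and `te_preset`.
#' @export
default_catalog <- function(te_preset = c("HERMES80", "MEGA120")) {
  te_preset <- match.arg(te_preset)

  line <- function(offset, amp_on, ph_on, amp_off, ph_off, dim) {
    data.frame(offset_ppm = offset, amp_on = amp_on, phase_on = ph_on,
               amp_off = amp_off, phase_off = ph_off, edit_dim = dim,
               stringsAsFactors = FALSE)
  }
  entry <- function(name, lines, t2_ms, gaussian_hz) {
    list(name = name, lines = lines, t2_ms = t2_ms, gaussian_hz = gaussian_hz)
  }

  # Aspartyl presets. At TE 80 the co-edited aspartyl response is a dense,
  # strongly phase-twisted multiplet (two doublets of doublets whose
  # J-evolution leaves neighbouring lines nearly antiphase) -- a lineshape a
  # Gaussian sum with one global phase cannot represent. At TE 120 the
  # multiplet has refocused to five near-absorptive lines.
  asp <- if (te_preset == "HERMES80") {
    # phases twist progressively; the lines adjacent to the 2.95-ppm GSH
    # doublet are close to antiphase, leaving a negative shoulder that makes
    # simple baseline placement under GSH ill-determined
    line(c(2.44, 2.50, 2.56, 2.62, 2.66, 2.72, 2.78, 2.84),
         c(0.2, 0.3, 0.35, 0.35, 0.35, 0.35, 0.3, 0.2),
         c(40, -65, 120, -150, -140, 160, -170, 175),
         -c(0.2, 0.3, 0.35, 0.35, 0.35, 0.35, 0.3, 0.2),
         c(40, -65, 120, -150, -140, 160, -170, 175), "gsh")
  } else {
    line(c(2.49, 2.56, 2.62, 2.68, 2.74), c(0.3, 0.5, 0.6, 0.5, 0.3),
         c(10, -8, 0, 12, -12), c(-0.3, -0.5, -0.6, -0.5, -0.3),
         c(10, -8, 0, 12, -12), "gsh")
  }

  # GSH editing efficiency: the 2.95-ppm doublet refocuses optimally near
  # TE = 120 ms; at the TE-80 Hadamard compromise the edited GSH signal is
  # weaker while the co-edited aspartyl response is not.
  gsh_eff <- if (te_preset == "HERMES80") 0.75 else 1.0
  entries <- list(
    GSH = entry("GSH",
      line(c(2.93, 2.97), gsh_eff * c(0.5, 0.5), 0,
           -gsh_eff * c(0.5, 0.5), 0, "gsh"),
      t2_ms = 150, gaussian_hz = 4),
    Asp = entry("Asp", asp, t2_ms = 120, gaussian_hz = 5),
    GABA = entry("GABA",
      line(c(2.98, 3.01, 3.04), c(0.25, 0.5, 0.25), 0,
           c(-0.25, -0.5, -0.25), 0, "gaba"),
      t2_ms = 200, gaussian_hz = 6),
    Glx = entry("Glx",
      line(c(3.71, 3.79), c(0.5, 0.5), 0, c(0.225, 0.225), 0, "gaba"),
      t2_ms = 150, gaussian_hz = 4),
    NAA = entry("NAA", line(2.008, 1, 0, 1, 0, "none"),
      t2_ms = 200, gaussian_hz = 4),
    tCr = entry("tCr", line(c(3.027, 3.913), c(1, 0.67), 0, c(1, 0.67), 0, "none"),
      t2_ms = 160, gaussian_hz = 4),
    # nine choline methyl protons -> amplitude 3 relative to the 3-proton
    # NAA/tCr methyl reference
    tCho = entry("tCho", line(3.20, 3, 0, 3, 0, "none"),
      t2_ms = 180, gaussian_hz = 4),
    # MM humps are modeled Gaussian-dominated (long T2, wide Gaussian) so
    # their tails fall off fast enough not to contaminate the alignment
    # target regions
    MM09 = entry("MM09", line(0.93, 1, 0, 0.4, 0, "gaba"),
      t2_ms = 200, gaussian_hz = 24),
    MM30 = entry("MM30", line(3.00, 1, 0, -0.2, 0, "gaba"),
      t2_ms = 200, gaussian_hz = 24),
    MM12 = entry("MM12", line(1.20, 1, 0, 0.3, 0, "gsh"),
      t2_ms = 200, gaussian_hz = 24),
    MM14 = entry("MM14", line(1.40, 1, 0, 0.3, 0, "gsh"),
      t2_ms = 200, gaussian_hz = 24),
    # Residual water after (imperfect) suppression: mildly editing-dependent so
    # a residual survives each difference target; its default concentration
    # makes the difference-spectrum water ~5x the GSH peak, so the HSVD filter
    # has real work to do.
    H2Oresid = entry("H2Oresid",
      rbind(line(4.68, 1, 0, 0.8, 0, "gsh"),
            line(4.683, 1, 0, 0.8, 0, "gaba")),
      t2_ms = 60, gaussian_hz = 8),
    # Unsuppressed water, used only for the water-reference acquisition.
    H2O = entry("H2O", line(4.68, 1, 0, 1, 0, "none"),
      t2_ms = 70, gaussian_hz = 6)
  )

  structure(list(entries = entries, te_preset = te_preset),
            class = "metabolite_catalog")
}

#' @export
print.metabolite_catalog <- function(x, ...) {
  cat(sprintf("<metabolite_catalog> %s: %d entries (%s)\n", x$te_preset,
              length(x$entries), paste(names(x$entries), collapse = ", ")))
  invisible(x)
}

#' Default ground-truth concentration means (mM-like arbitrary units)
#'
#' Plausible brain values for the metabolite entries plus macromolecule and
#' residual-water scales; `H2O` is the unsuppressed water reference scale.
#' @export
default_truth_means <- function() {
  c(GSH = 2.0, Asp = 2.5, GABA = 1.5, Glx = 12, NAA = 12, tCr = 7.5,
    tCho = 2.0, MM09 = 3.0, MM30 = 2.0, MM12 = 2.0, MM14 = 1.0,
    H2Oresid = 100, H2O = 30000)
}

#' Sub-experiment labels for a sequence
#' @param sequence_tag `"HERMES80"` or `"MEGA120"`.
#' @export
subexp_labels <- function(sequence_tag) {
  switch(sequence_tag,
         HERMES80 = c("A", "B", "C", "D"),
         MEGA120 = c("ON", "OFF"),
         stop("unknown sequence_tag: ", sequence_tag))
}

# Editing state (gaba, gsh) of a sub-experiment label.
subexp_state <- function(sequence_tag, label) {
  states <- switch(sequence_tag,
    HERMES80 = list(A = c(gaba = "on", gsh = "on"),
                    B = c(gaba = "on", gsh = "off"),
                    C = c(gaba = "off", gsh = "on"),
                    D = c(gaba = "off", gsh = "off")),
    MEGA120 = list(ON = c(gaba = "off", gsh = "on"),
                   OFF = c(gaba = "off", gsh = "off")),
    stop("unknown sequence_tag: ", sequence_tag))
  st <- states[[label]]
  if (is.null(st)) stop("unknown sub-experiment label: ", label)
  st
}

# Resolve one catalog entry to a plain multiplet for a given editing state.
# Signed amplitudes are folded into the phase (a < 0 -> +180 deg).
resolve_entry <- function(entry, state) {
  ln <- entry$lines
  use_on <- ifelse(ln$edit_dim == "none", TRUE, state[ln$edit_dim] == "on")
  amp <- ifelse(use_on, ln$amp_on, ln$amp_off)
  ph <- ifelse(use_on, ln$phase_on, ln$phase_off)
  ph <- ph + ifelse(amp < 0, 180, 0)
  keep <- abs(amp) > 0
  multiplet(entry$name,
            data.frame(offset_ppm = ln$offset_ppm[keep],
                       amplitude = abs(amp)[keep], phase_deg = ph[keep]),
            t2_ms = entry$t2_ms, gaussian_hz = entry$gaussian_hz)
}

#' Resolve a catalog to plain multiplets for one sub-experiment
#'
#' @param catalog A `metabolite_catalog`.
#' @param label Sub-experiment label (see [subexp_labels]).
#' @param exclude Entry names to drop (default the unsuppressed water entry).
#' @export
catalog_multiplets <- function(catalog, label, exclude = "H2O") {
  state <- subexp_state(catalog$te_preset, label)
  keep <- setdiff(names(catalog$entries), exclude)
  lapply(catalog$entries[keep], resolve_entry, state = state)
}

# Effective difference-spectrum lines of one entry under a target combination:
# complex coefficient per line = sum over sub-experiments of
# sign * a_state * exp(i phase_state) / n_subexp.
diff_lines <- function(entry, sequence_tag, target = c("GSH", "GABA")) {
  target <- match.arg(target)
  labels <- subexp_labels(sequence_tag)
  sgn <- if (sequence_tag == "HERMES80") {
    if (target == "GSH") c(A = 1, B = -1, C = 1, D = -1)
    else c(A = 1, B = 1, C = -1, D = -1)
  } else {
    if (target == "GABA") stop("MEGA120 has no GABA-targeted difference")
    c(ON = 1, OFF = -1)
  }
  ln <- entry$lines
  coef <- complex(real = rep(0, nrow(ln)))
  for (lab in labels) {
    state <- subexp_state(sequence_tag, lab)
    use_on <- ifelse(ln$edit_dim == "none", TRUE, state[ln$edit_dim] == "on")
    a <- ifelse(use_on, ln$amp_on, ln$amp_off)
    p <- ifelse(use_on, ln$phase_on, ln$phase_off)
    coef <- coef + sgn[[lab]] * a * exp(1i * p * pi / 180)
  }
  coef <- coef / length(labels)
  keep <- Mod(coef) > 1e-12
  data.frame(offset_ppm = ln$offset_ppm[keep], amplitude = Mod(coef)[keep],
             phase_deg = Arg(coef)[keep] * 180 / pi)
}

#' Noiseless difference-spectrum multiplet of one catalog entry
#'
#' Evaluates the target combination analytically on the entry's line table,
#' returning the effective multiplet that appears in the difference spectrum
#' at unit concentration (empty line table if the entry cancels).
#'
#' @param catalog A `metabolite_catalog`.
#' @param name Entry name.
#' @param target `"GSH"` or `"GABA"`.
#' @export
difference_multiplet <- function(catalog, name, target = c("GSH", "GABA")) {
  target <- match.arg(target)
  e <- catalog$entries[[name]]
  if (is.null(e)) stop("unknown catalog entry: ", name)
  multiplet(name, diff_lines(e, catalog$te_preset, target),
            t2_ms = e$t2_ms, gaussian_hz = e$gaussian_hz)
}
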