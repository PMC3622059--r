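#' Bath solution
#'
#' Composition of the extracellular solution. Extracellular chloride is
#' computed from the salts (`na + k + 2*ca + 2*mg`), on the assumption that
#' sodium and potassium enter as chloride salts and calcium and magnesium as
#' dichlorides. The default control saline (140 NaCl, 2.5 KCl, 2 CaCl2,
#' 2 MgCl2, HEPES-buffered, no bicarbonate) gives about 150 mM chloride.
#' All solutions carry 10 uM bumetanide so that NKCC1 is silent.
#'
#' @param na,k,ca,mg Salt concentrations, mM.
#' @param glycine,isoguvacine Agonist concentrations, uM (glycine gates GlyR,
#'   isoguvacine gates GABA-A receptors).
#' @param strychnine GlyR antagonist, uM.
#' @param furosemide Broad cation-chloride-cotransporter blocker, uM.
#' @param bumetanide Selective NKCC1 blocker, uM.
#' @param label Free-text name.
#' @return An object of class `bath_solution`.
#' @export
#' @examples
#' bath_solution()$cl_o  # control saline, ~150 mM chloride
bath_solution <- function(na = 140, k = 2.5, ca = 2, mg = 2,
                          glycine = 0, isoguvacine = 0,
                          strychnine = 0, furosemide = 0, bumetanide = 10,
                          label = "control") {
  stopifnot(na >= 0, k >= 0, ca >= 0, mg >= 0, glycine >= 0,
            isoguvacine >= 0, strychnine >= 0, furosemide >= 0,
            bumetanide >= 0)
  structure(list(na_o = na, k_o = k, ca_o = ca, mg_o = mg,
                 cl_o = na + k + 2 * ca + 2 * mg,
                 glycine = glycine, isoguvacine = isoguvacine,
                 strychnine = strychnine, furosemide = furosemide,
                 bumetanide = bumetanide, label = label),
            class = "bath_solution")
}

#' Named solution library
#'
#' The standard bath solutions used by the canned experiment
#' configurations. Depolarizing solutions substitute NaCl with an equimolar
#' amount of KCl, so total chloride is unchanged.
#'
#' @return A named list of [bath_solution()] objects: `control`,
#'   `control_strychnine`, `control_furosemide`, `glycine_kcl100` (50 uM
#'   glycine + 100 mM KCl), `glycine_kcl100_strychnine`, `kcl140`,
#'   `kcl140_furosemide`, `kcl25_isoguvacine` (25 mM KCl + 30 uM
#'   isoguvacine).
#' @export
solution_library <- function() {
  list(
    control = bath_solution(),
    control_strychnine = bath_solution(strychnine = 0.3,
                                       label = "control + strychnine"),
    control_furosemide = bath_solution(furosemide = 1000,
                                       label = "control + furosemide"),
    glycine_kcl100 = bath_solution(na = 42.5, k = 100, glycine = 50,
                                   label = "glycine + 100 KCl"),
    glycine_kcl100_strychnine = bath_solution(na = 42.5, k = 100,
                                              glycine = 50, strychnine = 0.3,
                                              label = "glycine + 100 KCl + strychnine"),
    kcl140 = bath_solution(na = 2.5, k = 140, label = "140 KCl"),
    kcl140_furosemide = bath_solution(na = 2.5, k = 140, furosemide = 1000,
                                      label = "140 KCl + furosemide"),
    kcl25_isoguvacine = bath_solution(na = 117.5, k = 25, isoguvacine = 30,
                                      label = "25 KCl + isoguvacine")
  )
}

#' Cellular compartment geometry
#'
#' Membrane flux terms scale with the compartment's surface-to-volume ratio
#' (per um) times an effective coupling factor; a spine neck limits exchange
#' and is modelled as reduced coupling rather than reduced area.
#'
#' @param name Compartment name (`"cell"`, `"soma"`, `"dendrite"`,
#'   `"spine"`, or free text).
#' @param volume Volume, fL (> 0).
#' @param surface Membrane surface, um^2 (> 0).
#' @param k_i Intracellular potassium, mM.
#' @param coupling Effective coupling factor in `(0, 1]`.
#' @return An object of class `compartment_spec`.
#' @seealso [compartment_presets()]
#' @export
compartment_spec <- function(name = "cell", volume = 1000, surface = 1000,
                             k_i = 140, coupling = 1) {
  stopifnot(volume > 0, surface > 0, k_i > 0, coupling > 0, coupling <= 1)
  structure(list(name = name, volume = volume, surface = surface,
                 k_i = k_i, coupling = coupling),
            class = "compartment_spec")
}

sv_eff <- function(comp) comp$surface / comp$volume * comp$coupling

#' Compartment presets for the neuron scene
#'
#' Effective surface-to-volume scaling: soma 1x, thin dendrite 6x, spine 3x
#' (high nominal surface-to-volume but neck-limited coupling). With shared
#' membrane parameters these produce chloride recovery half-times ordered
#' dendrite < spine < soma.
#'
#' @return A named list of [compartment_spec()] objects.
#' @export
compartment_presets <- function() {
  list(
    soma = compartment_spec("soma", volume = 1000, surface = 1000),
    dendrite = compartment_spec("dendrite", volume = 10, surface = 60),
    spine = compartment_spec("spine", volume = 0.1, surface = 1.2,
                             coupling = 0.25)
  )
}

#' Membrane transport parameters
#'
#' @param g_glyr,g_gabaar Channel strength of GlyR / GABA-A receptors,
#'   mM s^-1 mV^-1 at unit open probability and unit surface-to-volume.
#' @param p_tonic Tonic open-probability scale of the agonist-independent
#'   channel activity (lumping trace agonist contamination of the saline
#'   with any constitutive gating). Dimensionless, on the same scale as
#'   the agonist occupancy term; values above 1 are allowed.
#' @param u_kcc2,u_nkcc1 Cotransporter turnover, mM s^-1 at unit
#'   surface-to-volume per unit log chemical-potential term.
#' @param k_leak First-order leak rate towards `cl_leak`, s^-1.
#' @param cl_leak Leak equilibrium chloride, mM.
#' @param furosemide_block,bumetanide_block,strychnine_block Blocked
#'   fraction of KCC2+NKCC1 / NKCC1 / GlyR when the matching drug is in the
#'   bath, each in `[0, 1]`.
#' @param k50_glycine,k50_isoguvacine Agonist concentration, uM, at
#'   half-maximal receptor open probability.
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(g_glyr = 0, g_gabaar = 0, p_tonic = 0,
                             u_kcc2 = 0, u_nkcc1 = 0,
                             k_leak = 0, cl_leak = 9,
                             furosemide_block = 0.85,
                             bumetanide_block = 1,
                             strychnine_block = 1,
                             k50_glycine = 100, k50_isoguvacine = 10) {
  stopifnot(g_glyr >= 0, g_gabaar >= 0, p_tonic >= 0, u_kcc2 >= 0,
            u_nkcc1 >= 0, k_leak >= 0, cl_leak > 0,
            furosemide_block >= 0, furosemide_block <= 1,
            bumetanide_block >= 0, bumetanide_block <= 1,
            strychnine_block >= 0, strychnine_block <= 1)
  structure(as.list(environment()), class = "transport_params")
}

#' Membrane potential model
#'
#' Two-parameter mixture between the potassium Nernst potential and a fixed
#' offset: `vm = vm_weight * (-59.16 * log10(k_i / k_o)) +
#' (1 - vm_weight) * v_offset`, overridden by `clamp` when set. With the
#' defaults (weight 0.7, offset 0) the control saline gives about -72 mV
#' and full 140 mM KCl substitution gives 0 mV.
#'
#' @param vm_weight Mixing weight in `[0, 1]`.
#' @param v_offset Offset potential, mV.
#' @param clamp Optional voltage-clamp override, mV.
#' @return An object of class `membrane_model`.
#' @export
membrane_model <- function(vm_weight = 0.7, v_offset = 0, clamp = NULL) {
  stopifnot(vm_weight >= 0, vm_weight <= 1)
  structure(list(vm_weight = vm_weight, v_offset = v_offset, clamp = clamp),
            class = "membrane_model")
}

#' Chloride Nernst potential
#'
#' `E = -slope_mv * log10(cl_o / cl_i)`, with the 59.16 mV/decade slope of
#' the recording temperature.
#'
#' @param cl_o,cl_i Extra-/intracellular chloride, mM (> 0, vectorized).
#' @param slope_mv Nernst slope, mV per decade.
#' @return Reversal potential, mV.
#' @export
#' @examples
#' nernst_ecl(150, 15)   # one decade: -59.16 mV
nernst_ecl <- function(cl_o, cl_i, slope_mv = 59.16) {
  if (any(cl_o <= 0) || any(cl_i <= 0)) {
    stop("chloride concentrations must be positive")
  }
  -slope_mv * log10(cl_o / cl_i)
}

#' Invert the chloride Nernst relation
#'
#' Exact inverse of [nernst_ecl()]: returns the intracellular chloride
#' consistent with a measured reversal potential.
#'
#' @param e_mv Reversal potential, mV.
#' @param cl_o Extracellular chloride, mM (> 0).
#' @param slope_mv Nernst slope, mV per decade.
#' @return Intracellular chloride, mM.
#' @export
#' @examples
#' invert_nernst(-84, 150)  # ~5.70 mM
invert_nernst <- function(e_mv, cl_o, slope_mv = 59.16) {
  if (any(cl_o <= 0)) stop("cl_o must be positive")
  cl_o / 10^(-e_mv / slope_mv)
}

#' Ligand-gated channel chloride flux
#'
#' Contribution to `d[Cl]i/dt`: `g * p_open * (vm - e_cl)` scaled by the
#' compartment's effective surface-to-volume ratio. Positive (influx) when
#' the membrane is depolarized relative to the chloride reversal potential,
#' zero at reversal, negative (efflux) below it.
#'
#' @param g Channel strength, mM s^-1 mV^-1.
#' @param p_open Open probability in `[0, 1]`.
#' @param vm Membrane potential, mV.
#' @param e_cl Chloride reversal potential, mV.
#' @param comp A [compartment_spec()].
#' @return Flux, mM s^-1.
#' @export
channel_flux <- function(g, p_open, vm, e_cl, comp = compartment_spec()) {
  g * p_open * (vm - e_cl) * sv_eff(comp)
}

#' KCC2 / KCC-family cotransporter chloride flux
#'
#' Electroneutral K-Cl cotransport driven by the summed chemical potentials:
#' `-u * (1 - furosemide_factor * block) * ln((k_i * cl_i) / (k_o * cl_o))`
#' scaled by the compartment's effective surface-to-volume ratio. Zero at
#' product equality, efflux (negative) when the intracellular product is
#' larger, influx (positive, reverse mode) when high extracellular potassium
#' makes the extracellular product larger.
#'
#' @param k_o,cl_o,k_i,cl_i Ion concentrations, mM (> 0).
#' @param u Transporter turnover, mM s^-1.
#' @param furosemide_factor 1 when furosemide is in the bath, 0 otherwise
#'   (fractional occupancy allowed).
#' @param comp A [compartment_spec()].
#' @param block Blocked fraction at full furosemide, in `[0, 1]`.
#' @return Flux, mM s^-1.
#' @export
kcc2_flux <- function(k_o, cl_o, k_i, cl_i, u, furosemide_factor = 0,
                      comp = compartment_spec(), block = 0.85) {
  if (any(c(k_o, cl_o, k_i, cl_i) <= 0)) {
    stop("ion concentrations must be positive")
  }
  -u * (1 - furosemide_factor * block) *
    log((k_i * cl_i) / (k_o * cl_o)) * sv_eff(comp)
}

#' Membrane potential from bath potassium
#'
#' @param sol A [bath_solution()].
#' @param mm A [membrane_model()].
#' @param k_i Intracellular potassium, mM.
#' @return Membrane potential, mV (clamp value when set).
#' @export
#' @examples
#' membrane_potential(bath_solution(), membrane_model())  # ~ -72 mV
membrane_potential <- function(sol, mm = membrane_model(), k_i = 140) {
  if (!is.null(mm$clamp)) return(mm$clamp)
  stopifnot(sol$k_o > 0)
  mm$vm_weight * (-59.16 * log10(k_i / sol$k_o)) +
    (1 - mm$vm_weight) * mm$v_offset
}

glyr_open <- function(sol, tp) {
  # strychnine (0.3 uM) silences the tonic current driven by trace glycine;
  # a saturating 50 uM glycine application overcomes this competitive block
  block <- if (sol$strychnine > 0) 1 - tp$strychnine_block else 1
  agonist <- sol$glycine / (sol$glycine + tp$k50_glycine)
  tp$p_tonic * block + agonist
}

gabaar_open <- function(sol, tp) {
  tp$p_tonic + sol$isoguvacine / (sol$isoguvacine + tp$k50_isoguvacine)
}

total_cl_flux <- function(cl, sol, vm, tp, comp, u_scale = 1,
                          cl_leak = tp$cl_leak) {
  e_cl <- nernst_ecl(sol$cl_o, cl)
  furo <- as.numeric(sol$furosemide > 0)
  bume <- as.numeric(sol$bumetanide > 0)
  f_glyr <- channel_flux(tp$g_glyr, glyr_open(sol, tp), vm, e_cl, comp)
  f_gaba <- channel_flux(tp$g_gabaar, gabaar_open(sol, tp), vm, e_cl, comp)
  f_kcc2 <- kcc2_flux(sol$k_o, sol$cl_o, comp$k_i, cl,
                      tp$u_kcc2 * u_scale, furo, comp,
                      block = tp$furosemide_block)
  u_nkcc1_eff <- tp$u_nkcc1 * (1 - bume * tp$bumetanide_block) *
    (1 - furo * tp$furosemide_block)
  # NKCC1 runs down the summed Na + K + 2 Cl chemical potential
  f_nkcc1 <- if (u_nkcc1_eff > 0) {
    -u_nkcc1_eff * log((10 * comp$k_i * cl^2) /
                         (sol$na_o * sol$k_o * sol$cl_o^2)) * sv_eff(comp)
  } else 0
  f_leak <- tp$k_leak * (cl_leak - cl)
  f_glyr + f_gaba + f_kcc2 + f_nkcc1 + f_leak
}

#' Protocol event
#'
#' One timed change of recording conditions: a bath solution switch, an
#' optional voltage clamp, and/or an imposed intracellular chloride step
#' (used by calibration protocols to emulate loading through the patch
#' pipette).
#'
#' @param t_start_s Event onset, seconds.
#' @param solution A [bath_solution()] (or `NULL` to keep the previous one).
#' @param clamp_mv Optional voltage clamp, mV.
#' @param cl_set_mM Optional imposed intracellular chloride, mM; chloride in
#'   every compartment is reset to this value at the event onset.
#' @return A list of class `protocol_event`.
#' @export
protocol_event <- function(t_start_s, solution = NULL, clamp_mv = NULL,
                           cl_set_mM = NULL) {
  stopifnot(t_start_s >= 0)
  structure(list(t_start_s = t_start_s, solution = solution,
                 clamp_mv = clamp_mv, cl_set_mM = cl_set_mM),
            class = "protocol_event")
}

#' Simulate intracellular chloride dynamics
#'
#' Fixed-step explicit Euler integration of the summed channel, KCC2, NKCC1
#' and leak chloride fluxes across a list of compartments, driven by a
#' time-ordered protocol of bath/voltage events. Intracellular chloride is
#' floored at 0.1 mM. The integration is deterministic, and at the default
#' step the solution is converged (halving `dt` moves no output point by
#' more than 0.5%).
#'
#' @param protocol List of [protocol_event()]s, ordered by onset time. The
#'   first event must start at 0 and carry a solution.
#' @param tp A [transport_params()] object.
#' @param comps A list of [compartment_spec()]s (or a single one). Each may
#'   carry optional fields `cl_init`, `cl_leak` and `u_scale` to override
#'   the initial chloride, the leak equilibrium and the KCC2 turnover
#'   scaling per compartment.
#' @param dt Integration step, seconds (> 0).
#' @param t_end End time, seconds.
#' @param mm A [membrane_model()] used whenever no clamp is active.
#' @param record_every Record every n-th step (default 1).
#' @return A tibble with columns `time_s`, `compartment`, `cl_mM`, `vm_mV`,
#'   `solution`.
#' @export
#' @examples
#' prot <- list(protocol_event(0, bath_solution()))
#' out <- simulate_cli(prot, transport_params(k_leak = 1e-3, cl_leak = 9),
#'                     compartment_spec(), dt = 0.1, t_end = 10)
#' head(out)
simulate_cli <- function(protocol, tp, comps, dt = 0.1, t_end,
                         mm = membrane_model(), record_every = 1L) {
  if (dt <= 0) stop("dt must be positive")
  if (inherits(comps, "compartment_spec")) comps <- list(comps)
  t_ev <- vapply(protocol, function(e) e$t_start_s, numeric(1))
  if (is.unsorted(t_ev, strictly = TRUE)) {
    stop("protocol events must be strictly time-ordered")
  }
  if (t_ev[1] != 0 || is.null(protocol[[1]]$solution)) {
    stop("the first protocol event must start at t = 0 with a solution")
  }
  n_comp <- length(comps)
  cl <- vapply(comps, function(cc) {
    if (!is.null(cc$cl_init)) cc$cl_init else tp$cl_leak
  }, numeric(1))
  cl_leak <- vapply(comps, function(cc) {
    if (!is.null(cc$cl_leak)) cc$cl_leak else tp$cl_leak
  }, numeric(1))
  u_scale <- vapply(comps, function(cc) {
    if (!is.null(cc$u_scale)) cc$u_scale else 1
  }, numeric(1))
  sv <- vapply(comps, sv_eff, numeric(1))
  k_i_v <- vapply(comps, function(cc) cc$k_i, numeric(1))
  comp_names <- vapply(comps, function(cc) cc$name, character(1))
  if (anyDuplicated(comp_names)) {
    comp_names <- paste0(comp_names, "_", seq_len(n_comp))
  }

  steps <- seq(0, t_end, by = dt)
  n_steps <- length(steps)
  rec_idx <- seq(1, n_steps, by = record_every)
  out_cl <- matrix(NA_real_, nrow = length(rec_idx), ncol = n_comp)
  out_vm <- numeric(length(rec_idx))
  out_sol <- character(length(rec_idx))

  sol <- protocol[[1]]$solution
  clamp <- protocol[[1]]$clamp_mv
  if (!is.null(protocol[[1]]$cl_set_mM)) cl[] <- protocol[[1]]$cl_set_mM
  ev_i <- 1L
  rec_i <- 1L
  for (si in seq_len(n_steps)) {
    t_now <- steps[si]
    while (ev_i < length(protocol) &&
           t_now >= protocol[[ev_i + 1L]]$t_start_s - dt / 2) {
      ev_i <- ev_i + 1L
      ev <- protocol[[ev_i]]
      if (!is.null(ev$solution)) sol <- ev$solution
      clamp <- ev$clamp_mv
      if (!is.null(ev$cl_set_mM)) cl[] <- ev$cl_set_mM
    }
    vm <- if (!is.null(clamp)) clamp else {
      membrane_potential(sol, mm, k_i = comps[[1]]$k_i)
    }
    if ((si - 1L) %% record_every == 0L) {
      out_cl[rec_i, ] <- cl
      out_vm[rec_i] <- vm
      out_sol[rec_i] <- sol$label
      rec_i <- rec_i + 1L
    }
    # vectorized over compartments
    e_cl <- -59.16 * log10(sol$cl_o / cl)
    furo <- as.numeric(sol$furosemide > 0)
    p_ch <- tp$g_glyr * glyr_open(sol, tp) + tp$g_gabaar * gabaar_open(sol, tp)
    f_ch <- p_ch * (vm - e_cl) * sv
    f_kcc2 <- -tp$u_kcc2 * u_scale * (1 - furo * tp$furosemide_block) *
      log((k_i_v * cl) / (sol$k_o * sol$cl_o)) * sv
    u_nk <- tp$u_nkcc1 * (1 - as.numeric(sol$bumetanide > 0) * tp$bumetanide_block) *
      (1 - furo * tp$furosemide_block)
    f_nkcc1 <- if (u_nk > 0) {
      -u_nk * log((10 * k_i_v * cl^2) / (sol$na_o * sol$k_o * sol$cl_o^2)) * sv
    } else 0
    f_leak <- tp$k_leak * (cl_leak - cl)
    cl <- pmax(cl + dt * (f_ch + f_kcc2 + f_nkcc1 + f_leak), 0.1)
  }
  tibble::tibble(
    time_s = rep(steps[rec_idx], times = n_comp),
    compartment = rep(comp_names, each = length(rec_idx)),
    cl_mM = as.vector(out_cl),
    vm_mV = rep(out_vm, times = n_comp),
    solution = rep(out_sol, times = n_comp)
  )
}
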