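#' Self-consistent DMRG/FQ coupling
#'
#' The total energy of the coupled system is
#'
#'   E = E_DMRG + E_FQ + E_int,
#'
#' with E_DMRG the bare active-space energy (expectation of the unpolarized
#' Hamiltonian plus its core), E_FQ the classical charge energy and
#' E_int = sum_s q_s V_s(D) the electrostatic coupling built from the total
#' QM potential at the charge sites. The macro-iteration alternates (a) MPS
#' optimization under the charge-folded effective Hamiltonian, (b) orbital
#' rotation with FQ terms in the gradient, and (c) a polarized charge solve
#' with the QM potential as source, until both the total energy and the
#' charges are stationary. Densities are state-specific: the ground and
#' excited state each carry their own converged orbitals and charges.
#'
#' @name scf_coupler
NULL

#' Default run configuration
#'
#' @param n_active_electrons,n_active_orbitals active space definition.
#' @param ms2 spin projection (2Sz).
#' @param state "gs" or "es".
#' @param max_bond bond dimension M (single value) or schedule.
#' @param embedding "polarizable", "frozen" or "none".
#' @param tol_e energy threshold (Hartree), `tol_q` charge threshold.
#' @param max_macro macro-iteration limit.
#' @param damping charge mixing factor in (0, 1]; 1 = no damping. Engaged
#'   automatically (0.5) when the energy trace oscillates.
#' @param orbital_opt logical; alternate orbital optimization steps.
#' @param basis basis-set name for the built-in backend.
#' @param seed RNG seed used for MPS initialization.
#' @return configuration list.
#' @export
dmrgfq_config <- function(n_active_electrons, n_active_orbitals, ms2 = 0L,
                          state = "gs", max_bond = 32L,
                          embedding = "polarizable", tol_e = 1e-8,
                          tol_q = 1e-6, max_macro = 50L, damping = 1,
                          orbital_opt = TRUE, basis = "sto3g.s", seed = 1L) {
  list(n_active_electrons = n_active_electrons,
       n_active_orbitals = n_active_orbitals, ms2 = ms2, state = state,
       max_bond = max_bond, embedding = embedding, tol_e = tol_e,
       tol_q = tol_q, max_macro = max_macro, damping = damping,
       orbital_opt = orbital_opt, basis = basis, seed = seed)
}

#' Read a run configuration file (YAML)
#' @param path file path.
#' @return configuration list (defaults filled in).
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  do.call(dmrgfq_config, doc)
}

# build backend objects for a QM specification
qm_context <- function(qm, config) {
  if (!is.null(qm[["fcidump"]]))
    return(list(mode = "fcidump", ints = read_fcidump(qm[["fcidump"]])))
  # exact-name indexing: $ would partial-match positions_ang
  positions <- qm[["positions"]]
  if (is.null(positions))
    positions <- qm[["positions_ang"]] * ANGSTROM_TO_BOHR
  nuclei <- list(Z = unname(vapply(qm$elements, element_charge, numeric(1))),
                 positions = as.matrix(positions))
  basis <- build_basis(qm$elements, nuclei$positions,
                       qm[["basis"]] %||% config$basis)
  ao <- ao_integrals(basis, nuclei)
  n_elec_tot <- sum(nuclei$Z) - (qm[["charge"]] %||% 0)
  list(mode = "backend", nuclei = nuclei, basis = basis, ao = ao,
       n_electrons_total = n_elec_tot)
}

default_partition <- function(n_mo, n_act_orb, n_elec_tot, n_act_el) {
  n_inact <- (n_elec_tot - n_act_el) / 2
  if (n_inact != round(n_inact) || n_inact < 0)
    stop("inconsistent electron counts for the requested active space")
  n_inact <- as.integer(n_inact)
  if (n_inact + n_act_orb > n_mo) stop("active space larger than MO space")
  list(inactive = seq_len(n_inact),
       active = n_inact + seq_len(n_act_orb),
       virtual = setdiff(seq_len(n_mo), seq_len(n_inact + n_act_orb)))
}

#' State-specific DMRG/FQ (or gas-phase DMRGSCF) calculation
#'
#' Implements the coupled protocol: starting orbitals; initial MPS and
#' densities; initial charges from the polarized solve; then macro-iterations
#' of MPS update with the effective Hamiltonian, orbital update with FQ
#' gradient terms, and charge update, until |dE| < tol_e and max|dq| < tol_q.
#'
#' @param qm QM region specification: either `list(fcidump = path)`
#'   (gas-phase only) or `list(elements=, positions=/positions_ang=,
#'   charge=, basis=)` for the built-in backend.
#' @param fq an `fq_system` for the classical region, or NULL.
#' @param config configuration from [dmrgfq_config()].
#' @param orbitals optional starting `orbital_set` (e.g. from a ground-state
#'   run when targeting the excited state).
#' @param frozen_charges charge vector for `embedding = "frozen"`.
#' @return object of class `coupling_state` with fields `state_label`,
#'   `energy_total`, `energy_dmrg`, `energy_fq`, `energy_interaction`,
#'   `charges`, `multipliers`, `orbitals`, `mps`, `density`,
#'   `convergence_trace`, `converged`, `n_macro`, plus backend context.
#' @export
run_dmrgscf_fq <- function(qm, fq = NULL, config, orbitals = NULL,
                           frozen_charges = NULL) {
  set.seed(config$seed)
  root <- if (identical(config$state, "es")) 2L else 1L
  ctx <- qm_context(qm, config)
  embedding <- config$embedding
  if (is.null(fq)) embedding <- "none"

  if (ctx$mode == "fcidump") {
    if (embedding != "none")
      stop("FCIDUMP input supports gas-phase runs only (no ESP operators)")
    sol <- solve_state(ctx$ints, root = root, max_bond = config$max_bond)
    rdms <- compute_rdms(sol$mps)
    return(structure(list(
      state_label = config$state, energy_total = sol$energy_total,
      energy_dmrg = sol$energy_total, energy_fq = 0, energy_interaction = 0,
      charges = numeric(0), multipliers = numeric(0), orbitals = NULL,
      mps = sol$mps, density = rdms, convergence_trace = sol$energy_total,
      converged = sol$converged, n_macro = 1L, context = ctx,
      solution = sol), class = "coupling_state"))
  }

  ao <- ctx$ao
  nel_act <- config$n_active_electrons
  norb_act <- config$n_active_orbitals
  part <- default_partition(ao$n_ao, norb_act, ctx$n_electrons_total, nel_act)
  if (is.null(orbitals)) {
    hf <- rhf(ao, ctx$n_electrons_total)
    orbitals <- orbital_set(hf$coefficients, part, ao$S)
  }

  esp_ao <- NULL; sites <- NULL
  if (embedding != "none") {
    sites <- fq$atoms$positions
    esp_ao <- ao_esp_matrices(ctx$basis, sites)
  }
  vnuc_sites <- if (embedding != "none")
    nuclear_potential_at_sites(ctx$nuclei, sites) else numeric(0)

  solve_qm <- function(orbs, q, guess = NULL, macro_budget = 25L) {
    e_cn <- if (length(q) > 0L) sum(q * vnuc_sites) else 0
    if (config$orbital_opt) {
      optimize_orbitals(ao, orbs, nel_act, config$ms2, root = root,
                        max_bond = config$max_bond,
                        charges = if (length(q)) q else NULL,
                        esp_ao = esp_ao, e_charge_nuc = e_cn,
                        max_macro = macro_budget, tol = 1e-7,
                        mps_guess = guess)
    } else {
      h_ao <- fold_charges_ao(ao$hcore, if (length(q)) q else NULL, esp_ao)
      ints <- transform_to_active(ao, orbs, nel_act, config$ms2,
                                  h_extra_ao = h_ao - ao$hcore)
      ints$core_energy <- ints$core_energy + e_cn
      sol <- solve_state(ints, root = root, max_bond = config$max_bond,
                         guess = guess)
      list(energy = sol$energy_total, orbitals = orbs,
           mps = sol$mps, rdms = compute_rdms(sol$mps), ints = ints,
           gradient_norm = NA_real_, converged = sol$converged,
           solution = sol)
    }
  }

  # gas phase: a single orbital-optimized solve is the whole calculation
  if (embedding == "none") {
    res <- solve_qm(orbitals, numeric(0))
    return(structure(list(
      state_label = config$state, energy_total = res$energy,
      energy_dmrg = res$energy, energy_fq = 0, energy_interaction = 0,
      charges = numeric(0), multipliers = numeric(0),
      orbitals = res$orbitals, mps = res$mps, density = res$rdms,
      convergence_trace = res$trace %||% res$energy,
      converged = res$converged, n_macro = length(res$trace %||% 1),
      context = ctx, partition = part, solution = res),
      class = "coupling_state"))
  }

  # step 1-2: starting orbitals, initial MPS and densities (unpolarized)
  res <- solve_qm(orbitals, numeric(0), macro_budget = 15L)
  esp <- electronic_esp_matrices(ctx$basis, ctx$nuclei, res$orbitals, sites)
  # step 3: initial charges from the polarized solve (Eq-17-type system)
  if (embedding == "frozen") {
    if (is.null(frozen_charges)) stop("frozen embedding requires charges")
    q <- frozen_charges
    lambda <- numeric(length(fq$groups))
  } else {
    v_d <- esp_potential_of_density(esp, res$rdms$one_particle)
    fq <- solve_fq(fq, v_d)
    q <- fq$charges; lambda <- fq$multipliers
  }

  e_total_of <- function(res, q, esp) {
    e_dmrg <- bare_qm_energy(res, ao, orbitals_of(res), q, esp_ao, vnuc_sites)
    e_int <- interaction_energy(q, esp, res$rdms$one_particle)
    e_fq <- fq_energy(q, fq$atoms$chi, fq$kernel)
    c(total = unname(e_dmrg + e_int + e_fq), dmrg = unname(e_dmrg),
      int = unname(e_int), fq = unname(e_fq))
  }

  trace <- numeric(0)
  damping <- config$damping
  e_prev <- Inf
  converged <- FALSE
  parts <- NULL
  for (k in seq_len(config$max_macro)) {
    # (a)+(b): MPS and orbital update under the charge-folded Hamiltonian
    res <- solve_qm(res$orbitals, q, macro_budget = if (k == 1L) 20L else 8L)
    esp <- electronic_esp_matrices(ctx$basis, ctx$nuclei, res$orbitals, sites)
    # (c): charge update from the polarized solve
    if (embedding == "polarizable") {
      v_d <- esp_potential_of_density(esp, res$rdms$one_particle)
      fq <- solve_fq(fq, v_d)
      q_new <- damping * fq$charges + (1 - damping) * q
      lambda <- fq$multipliers
    } else q_new <- q
    parts <- e_total_of(res, q_new, esp)
    trace <- c(trace, parts["total"])
    dq <- if (length(q)) max(abs(q_new - q)) else 0
    de <- abs(parts["total"] - e_prev)
    if (k > 1L && parts["total"] > e_prev + 1e-12 && damping > 0.5) {
      damping <- 0.5  # oscillation detected: engage charge mixing
      message("energy rose at macro-iteration ", k, "; damping engaged")
    }
    q <- q_new
    if (de < config$tol_e && dq < config$tol_q) { converged <- TRUE; break }
    e_prev <- parts["total"]
  }
  if (!converged)
    warning("DMRG/FQ macro-iteration limit reached; returning best iterate")

  structure(list(
    state_label = config$state, energy_total = unname(parts["total"]),
    energy_dmrg = unname(parts["dmrg"]), energy_fq = unname(parts["fq"]),
    energy_interaction = unname(parts["int"]), charges = q,
    multipliers = lambda, orbitals = res$orbitals, mps = res$mps,
    density = res$rdms, convergence_trace = trace, converged = converged,
    n_macro = length(trace), context = ctx, partition = part, esp = esp,
    fq = fq, solution = res), class = "coupling_state")
}

orbitals_of <- function(res) res$orbitals

# bare (unpolarized) QM energy <Psi|H|Psi> + core for a solved state:
# rebuild the gas-phase integrals at the converged orbitals and contract
# with the state's densities
bare_qm_energy <- function(res, ao, orbitals, q, esp_ao, vnuc_sites) {
  ints_bare <- transform_to_active(ao, orbitals,
                                   res$ints$n_electrons, res$ints$ms2)
  rdm_energy(res$rdms, ints_bare)
}

#' Re-assemble the total DMRG/FQ energy functional for a perturbed charge
#' vector
#'
#' Evaluates the full Lagrangian energy functional E(D, P, q, lambda) at the
#' state's converged densities and multipliers but arbitrary charges, without
#' re-solving anything. The constraint term lambda_a (sum_i q_ia - Q_a)
#' vanishes for feasible charges and makes the functional stationary in every
#' charge direction at the converged solution. Used for stationarity
#' diagnostics.
#'
#' @param state a converged `coupling_state`.
#' @param charges charge vector.
#' @return total functional value (Hartree).
#' @export
assemble_energy <- function(state, charges) {
  constraint <- 0
  for (g in seq_along(state$fq$groups)) {
    grp <- state$fq$groups[[g]]
    constraint <- constraint + state$multipliers[g] *
      (sum(charges[grp$atom_indices]) - grp$total_charge)
  }
  state$energy_dmrg +
    interaction_energy(charges, state$esp, state$density$one_particle) +
    fq_energy(charges, state$fq$atoms$chi, state$fq$kernel) + constraint
}

#' Vertical excitation energy from two converged states
#'
#' @param gs,es converged `coupling_state` objects for the ground and
#'   excited state (same geometry and FQ parameterization).
#' @return excitation energy in eV. A negative gap is returned with a
#'   root-flip warning, never silently.
#' @export
excitation_energy <- function(gs, es) {
  if (!isTRUE(gs$converged) || !isTRUE(es$converged))
    stop("excitation_energy requires converged states")
  gap <- (es$energy_total - gs$energy_total) * HARTREE_TO_EV
  if (gap < 0)
    warning("negative excitation energy: probable root flip between states")
  gap
}

#' Save a coupling-state checkpoint (RDS container)
#' @param state a `coupling_state`.
#' @param path output path.
#' @export
save_coupling_state <- function(state, path) {
  saveRDS(state, path); invisible(path)
}

#' Load a coupling-state checkpoint
#' @param path checkpoint path.
#' @return a `coupling_state`.
#' @export
load_coupling_state <- function(path) readRDS(path)
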