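#' Baseline constants of the human atrial myocyte model
#'
#' Returns the full constant set of the Maleckar-type human atrial ionic
#' model used throughout the package (Nygren-lineage formulation with
#' reformulated transient-outward and ultrarapid potassium currents,
#' no constant inward Na+ leak, stimulus charge booked to intracellular K+).
#' This named vector is the versioned reference parameter set: the regional
#' variants only rescale \code{g_t}, \code{g_CaL} and \code{g_Kr}.
#'
#' Units: conductances nS, permeability nL/s, currents pA, concentrations mM,
#' volumes nL, time constants of ionic buffering/diffusion s, capacitance pF,
#' temperature K.
#'
#' @return Named numeric vector of model constants.
#' @export
maleckarConstants <- function() {
  c(
    R = 8314, T = 306.15, F = 96487, Cm = 50,
    P_Na = 0.0018,
    g_CaL = 6.75, E_Ca_app = 60, k_Ca = 0.025,
    g_t = 8.25, g_kur = 2.25,
    g_K1 = 3.1, g_Ks = 1, g_Kr = 0.5,
    g_B_Na = 0.060599, g_B_Ca = 0.078681,
    K_NaK_K = 1, i_NaK_max = 68.55, K_NaK_Na = 11,
    i_CaP_max = 4, k_CaP = 0.0002,
    K_NaCa = 0.0374842, gamma_Na = 0.45, d_NaCa = 0.0003,
    phi_Na_en = 0,
    Vol_i = 0.005884, Vol_c = 0.000800224, Vol_d = 0.00011768,
    Vol_rel = 0.0000441, Vol_up = 0.0003969,
    tau_Na = 14.3, tau_K = 10, tau_Ca = 24.7,
    Na_b = 130, K_b = 5.4, Ca_b = 1.8,
    Mg_i = 2.5,
    I_up_max = 2800, k_cyca = 0.0003, k_srca = 0.5, k_xcs = 0.4,
    tau_tr = 0.01, alpha_rel = 200000, r_recov = 0.815, tau_di = 0.01,
    ACh = 1e-24
  )
}

#' Names of the model state variables, in solver order
#'
#' @return Character vector of length 29.
#' @export
maleckarStateNames <- function() {
  c("V", "Na_c", "Na_i", "K_c", "K_i", "Ca_c", "Ca_i", "Ca_d",
    "Ca_up", "Ca_rel",
    "m", "h1", "h2", "d_L", "f_L1", "f_L2", "r", "s", "a_ur", "i_ur",
    "n", "pa",
    "F1", "F2", "O_C", "O_TC", "O_TMgC", "O_TMgMg", "O_Calse")
}

#' Default (unpaced) initial state of the ionic model
#'
#' Quiescent state of this formulation, obtained by integrating the
#' unstimulated baseline model for 60 s so that residual resting drift is
#' below 0.1 mV/s; long pacing protocols erase any remaining sensitivity
#' to these values.
#'
#' @return Named numeric vector (see [maleckarStateNames()]).
#' @export
maleckarInitialState <- function() {
  x <- c(
    V = -76.5847497,
    Na_c = 130.938505, Na_i = 7.96206067,
    K_c = 4.71847763, K_i = 130.123595,
    Ca_c = 1.85683737, Ca_i = 4.87814531e-05, Ca_d = 5.23093815e-05,
    Ca_up = 0.493915644, Ca_rel = 0.486205868,
    m = 0.0024118675, h1 = 0.920566707, h2 = 0.920593346,
    d_L = 8.69675681e-06, f_L1 = 0.999020472, f_L2 = 0.999020627,
    r = 0.000863923593, s = 0.958426684,
    a_ur = 0.000272512913, i_ur = 0.999009079,
    n = 0.000501014655, pa = 3.48565585e-05,
    F1 = 0.910226786, F2 = 0.00208303097,
    O_C = 0.0200848101, O_TC = 0.00966206468, O_TMgC = 0.148060536,
    O_TMgMg = 0.751799706, O_Calse = 0.368466844
  )
  stopifnot(identical(names(x), maleckarStateNames()))
  x
}
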