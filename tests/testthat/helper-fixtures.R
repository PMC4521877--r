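# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code; nothing is read from disk.

fix_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fix_env)) assign(name, builder(), envir = fix_env)
  get(name, envir = fix_env)
}

# the standard test heart: moderately dilated LV + crescent RV
heart_mesh <- function() {
  fixture("heart", function() {
    build_biventricular_mesh(anatomy_config(edge_length = 12))
  })
}

heart_fibers <- function() fixture("hfib", function() generate_fibers(heart_mesh()))

heart_torso <- function() fixture("htorso", function() build_torso(heart_mesh()))

# full-beat EP solution (covers repolarization)
heart_sol <- function() {
  fixture("hsol", function() {
    simulate_ep(heart_mesh(), heart_fibers(), ep_parameters(),
                sinus_protocol(heart_mesh()), duration = 450, dt = 0.1)
  })
}

heart_trace <- function() {
  fixture("htrace", function() {
    compute_ecg(heart_sol(), heart_mesh(), heart_fibers(), ep_parameters(),
                heart_torso())
  })
}

heart_beat <- function() {
  fixture("hbeat", function() {
    simulate_beat(heart_mesh(), heart_fibers(), heart_sol(),
                  mech_parameters(), hemo_parameters(), early_stop = TRUE)
  })
}

# a coarser heart for the multi-patient personalization study
coarse_mesh <- function() {
  fixture("coarse", function() {
    build_biventricular_mesh(anatomy_config(edge_length = 14))
  })
}

# self-consistent EP recovery (expensive; shared between the acceptance
# suite and the personalization tests)
ep_recovery_fit <- function() {
  fixture("ep_fit", function() {
    fwd <- ep_forward_pipeline(heart_mesh(), heart_fibers(), heart_torso())
    truth <- ep_parameters(c_myo = 650, c_lv = 2000, c_rv = 1800,
                           tau_close = 185)
    tf <- fwd(truth, full = TRUE)
    targets <- clinical_targets(m_qrsd = tf$qrsd, m_ea = tf$ea,
                                m_qt = tf$qtd)
    list(fit = personalize_ep(targets, fwd, init = ep_parameters()),
         truth = truth, truth_features = tf, forward = fwd)
  })
}

# self-consistent (E, sigma0) recovery (expensive, shared likewise)
mech_recovery_fit <- function() {
  fixture("mech_fit", function() {
    fwd <- mech_forward_pipeline(heart_mesh(), heart_fibers(), heart_sol())
    truth <- fwd(700, 350)
    targets <- clinical_targets(ef = truth$EF, sv = truth$SV,
                                edv = truth$EDV, esv = truth$ESV,
                                edp = truth$EDP, esp = truth$ESP)
    list(fit = personalize_mechanics(targets, fwd, init = c(590, 295),
                                     maxit = 25),
         truth = truth, forward = fwd)
  })
}

# uniform fiber field for slab experiments
uniform_fiber_field <- function(mesh, dir = c(1, 0, 0)) {
  structure(list(vectors = matrix(rep(dir, nrow(mesh$tets)), ncol = 3,
                                  byrow = TRUE),
                 angle = rep(0, nrow(mesh$tets)), rule = fiber_rule(),
                 n_degenerate = 0),
            class = "fiber_field")
}

# plane-wave stimulus from a labeled box face
face_protocol <- function(mesh, face = "XMIN") {
  stimulus_protocol(list(list(nodes = surface_nodes(mesh, face), onset = 0,
                              duration = 1, amplitude = 2)))
}
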