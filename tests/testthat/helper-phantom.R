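# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_mesh <- function() fixture("mesh3", function() build_mesh("icosphere", 3))
small_atlas <- function() fixture("atlas3", function() build_atlas(small_mesh()))

paper_tes <- function() c(2.53, 7.03, 12.55, 20.35) / 1000

# population with every subject-level variance source switched off
frozen_population <- function(...) {
  population_params(inter_subject_sd = 0, global_sd_r1 = 0,
                    global_sd_t2s = 0, t1w_gain_sd = 0,
                    subject_spatial_sd = 0, vein_fraction = 0, ...)
}

# the full default experiment (icosphere resolution 4, 10 subjects,
# 3 rescans), shared by the end-to-end checks
acceptance_bundle <- function() {
  fixture("bundle_default", function() {
    run_experiment(experiment_config(seed = 1L), verbose = FALSE)
  })
}

# a small cohort on the res-3 sphere for tests that need sessions
small_cohort <- function() {
  fixture("cohort3", function() {
    mesh <- small_mesh()
    atlas <- small_atlas()
    pop <- population_params()
    acq <- acquisition_spec()
    sessions <- lapply(1:4, function(s) {
      gt <- sample_ground_truth(mesh, atlas, pop, 100 + s)
      list(s1 = simulate_session(gt, acq, 200 + s),
           s2 = simulate_session(gt, acq, 300 + s))
    })
    list(mesh = mesh, atlas = atlas, pop = pop, acq = acq,
         sessions = sessions)
  })
}
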