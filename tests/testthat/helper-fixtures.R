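# shared fixtures, built in code

# a small session design with ITIs drawn from the standard choices
make_design <- function(nt = 10, seed = 1, reinforced = rep(FALSE, nt),
                        iti = c(7, 8, 9, 10, 11)) {
  set.seed(seed)
  itis <- sample(iti, nt, replace = TRUE)
  on <- 10 + cumsum(c(0, (4 + itis)[-nt]))
  session_design(on, rep(c("CS+", "CS-"), length.out = nt), reinforced)
}

# well-posed ground-truth parameters on a design
make_params <- function(design, seed = 2, scl = 0) {
  set.seed(seed)
  nt <- n_trials(design)
  on <- design$trials$cs_onset
  trial_params(design,
               amp_ant = runif(nt, 0.5, 1.5),
               onset_ant = on + runif(nt, 0.3, 3.2),
               disp_ant = 0.3,
               amp_evoked = runif(nt, 0.5, 1.5),
               scl_change = if (length(scl) == 1 && scl == 0) NULL
                            else scl)
}

# a noise-free recording rendered from known parameters
make_clean_recording <- function(design, params, rate = 10) {
  predict_scr(params, design, canonical_rf(), rate = rate,
              duration = max(design$trials$cs_onset) + 40)
}

# cache for expensive shared computations (cohort analyses reused across
# acceptance properties)
.scrdcm_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.scrdcm_test_cache[[key]]))
    .scrdcm_test_cache[[key]] <- force(expr)
  .scrdcm_test_cache[[key]]
}
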