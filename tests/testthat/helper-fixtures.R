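# Shared fixtures for the test suite.

# Validation-simulation sequence settings (TR 5 ms, FA 15 deg, k 20,
# T_FS 50 ms, T_BS 12 ms, T_Sp 6 ms) and the four tissue pairs the signal
# model is validated on.
validation_seq <- function() {
  seq_params(TR = 5, alpha = 15, k = 20, T_FS = 50, T_BS = 12, T_Sp = 6)
}

validation_tissues <- function() {
  pairs <- expand.grid(T1 = c(500, 1500), T2 = c(25, 50))
  lapply(seq_len(nrow(pairs)), function(i)
    tissue_params(pairs$T1[i], pairs$T2[i], 1))
}

# random physically plausible tissue/sequence draws for property tests
random_tissue <- function() {
  T1 <- runif(1, 150, 3000)
  tissue_params(T1, runif(1, 15, min(T1, 350)), runif(1, 0.1, 5))
}

random_spgr_seq <- function() {
  seq_params(TR = runif(1, 2, 20), alpha = runif(1, 1, 40),
             k = sample(5:40, 1))
}

# tiny phantom for fast fitting tests
small_phantom <- function(grid_dim = c(24, 24, 1)) {
  make_phantom(grid_dim = grid_dim)
}
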