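# Shared fixtures, all generated in code at test time.

# Clean (noise-free) synthetic recording with exact ground truth.
clean_synth <- function(duration = 12, fs = 1000, seed = 3,
                        resp = 0.2) {
  p <- scg_subject_params(noise_sd = 0, resp_mod_depth = resp)
  synthesize(p, duration, fs = fs, seed = seed)
}

# One fully annotated toy beat at round sample positions (fs = 1000).
toy_beat <- function() {
  scg_annotations(
    beat = rep(1L, 9),
    label = c("Cs", "Ds", "Fs", "Gs", "Ks", "Ls", "Cd", "Dd", "Ed"),
    sample = c(100L, 150L, 200L, 250L, 300L, 350L, 500L, 550L, 600L))
}

# Probability segmaps with given binary rows (rows default to zero).
prob_maps <- function(n, fs, rows = list()) {
  m <- matrix(0, 19, n)
  for (nm in names(rows)) m[as.integer(nm), ] <- rows[[nm]]
  scgdelin:::new_segmaps(m, fs)
}

# Binary vector with ones on the given inclusive runs.
runs_vec <- function(n, runs) {
  x <- numeric(n)
  for (r in runs) x[r[1]:r[2]] <- 1
  x
}

# Brute-force independent run finder used as an oracle against the
# package's run-length machinery.
oracle_runs <- function(x) {
  idx <- which(x != 0)
  if (!length(idx)) return(data.frame(start = integer(0),
                                      end = integer(0)))
  brk <- c(0, which(diff(idx) > 1), length(idx))
  data.frame(start = idx[head(brk, -1) + 1], end = idx[brk[-1]])
}
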