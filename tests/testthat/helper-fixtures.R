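# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# quiet labeled-mode optics on a small 64x64-px field
fix_optics <- function(...) optics_config(mode = "labeled", ...)

fix_af647 <- function() dye_library("AF647")

# small noisy labeled stack with clean slots, 40 frames
fix_stack_small <- function() fixture("stack_small", function() {
  simulate_stack(fix_optics(), fix_af647(), n_frames = 40, density = 0.1,
                 seed = 101, keep_clean = TRUE)
})

# noise-free stack for geometric checks
fix_stack_clean <- function() fixture("stack_clean", function() {
  simulate_stack(fix_optics(background_rate = 0, read_noise_sd = 0),
                 fix_af647(), n_frames = 6, density = 0.1, seed = 7,
                 add_noise = FALSE)
})

# exhaustive optimal matcher used as the independent oracle for
# match_localizations (all subsets x permutations; fine for <= 8 points)
oracle_match <- function(P, Tr, radius) {
  np <- nrow(P)
  nt <- nrow(Tr)
  if (np == 0 || nt == 0) return(list(tp = 0L, dist = 0))
  D <- sqrt(outer(P[, 1], Tr[, 1], "-")^2 + outer(P[, 2], Tr[, 2], "-")^2)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- list(tp = -1L, dist = Inf)
  for (k in 0:min(np, nt)) {
    for (cp in utils::combn(np, k, simplify = FALSE))
      for (ct in utils::combn(nt, k, simplify = FALSE))
        for (pp in perms(ct)) {
          d <- D[cbind(cp, pp)]
          if (all(d <= radius)) {
            tot <- sum(d)
            if (k > best$tp || (k == best$tp && tot < best$dist))
              best <- list(tp = as.integer(k), dist = tot)
          }
        }
  }
  best
}
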