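## Independent oracles used by the thermodynamics tests. These deliberately
## avoid the package's affine-state dynamic program: the duplex energy is
## recomputed by explicit enumeration over every predecessor column (every
## contiguous-stack decomposition), and the equilibrium yield by interval
## bisection instead of the closed-form quadratic root.

## Minimum duplex free energy by brute-force predecessor enumeration.
## Energy model (must mirror the documented one): alignment of a against
## c = revcomp(b); aligned WC columns may start/end the duplex; adjacent WC
## columns add the nearest-neighbor stack of a's dinucleotide; internal
## mismatch columns cost `mm` each; a jump leaving g >= 1 unpaired interior
## bases costs open + ext * g; one initiation term; overhangs free.
brute_force_duplex_dg <- function(a, b, params = nn_params(),
                                  temperature_celsius = 25) {
  if (nchar(a) < 2L || nchar(b) < 2L) return(Inf)
  sm <- hybriclass:::stack_dg_matrix(params, temperature_celsius)
  tk <- temperature_celsius + 273.15
  init <- params$init_dH - tk * params$init_dS / 1000
  mm <- params$mismatch_penalty_dG
  open <- params$loop_open_dG
  ext <- params$loop_extend_dG

  ai <- match(strsplit(a, "")[[1L]], c("A", "T", "C", "G"))
  ci <- match(strsplit(reverse_complement(b), "")[[1L]],
              c("A", "T", "C", "G"))
  n <- length(ai); m <- length(ci)
  E <- matrix(Inf, n, m)
  wc <- outer(ai, ci, "==")
  for (i in seq_len(n)) {
    for (k in seq_len(m)) {
      col_cost <- if (wc[i, k]) 0 else mm
      best <- if (wc[i, k]) init else Inf   # only WC columns may start
      if (i > 1L && k > 1L) {
        ip <- 1:(i - 1L); kp <- 1:(k - 1L)
        prev <- E[ip, kp, drop = FALSE]
        gaps <- outer(i - ip - 1L, k - kp - 1L, "+")
        trans <- matrix(open + ext * gaps, i - 1L, k - 1L)
        ## the (i-1, k-1) predecessor is adjacent: stack or nothing, no loop
        trans[i - 1L, k - 1L] <-
          if (wc[i, k] && wc[i - 1L, k - 1L]) sm[ai[i - 1L], ai[i]] else 0
        best <- min(best, min(prev + trans))
      }
      E[i, k] <- col_cost + best
    }
  }
  if (!any(wc)) return(Inf)
  min(E[wc])
}

## Best energy over purely ungapped offset registrations (no interior
## loops); an upper bound on the full model's optimum.
ungapped_offset_dg <- function(a, b, params = nn_params(),
                               temperature_celsius = 25) {
  if (nchar(a) < 2L || nchar(b) < 2L) return(Inf)
  sm <- hybriclass:::stack_dg_matrix(params, temperature_celsius)
  tk <- temperature_celsius + 273.15
  init <- params$init_dH - tk * params$init_dS / 1000
  mm <- params$mismatch_penalty_dG
  ai <- match(strsplit(a, "")[[1L]], c("A", "T", "C", "G"))
  ci <- match(strsplit(reverse_complement(b), "")[[1L]],
              c("A", "T", "C", "G"))
  n <- length(ai); m <- length(ci)
  best <- Inf
  for (off in (-(m - 1L)):(n - 1L)) {
    i <- max(1L, 1L + off):min(n, m + off)
    k <- i - off
    ok <- ai[i] == ci[k]
    if (!any(ok)) next
    span <- which(ok)
    ## optimal sub-interval of aligned columns: ends must be WC
    for (s in span) {
      for (e in span[span >= s]) {
        cols <- s:e
        mism <- sum(!ok[cols])
        stacks <- 0
        for (t in cols[-length(cols)]) {
          if (ok[t] && ok[t + 1L]) stacks <- stacks + sm[ai[i[t]], ai[i[t + 1L]]]
        }
        best <- min(best, init + mism * mm + stacks)
      }
    }
  }
  best
}

## Equilibrium yield by bisection on K*c0*(1-y)^2 = y.
bisection_yield <- function(delta_g, conditions = hybridization_conditions(),
                            tol = 1e-13) {
  if (is.infinite(delta_g) && delta_g > 0) return(0)
  tk <- conditions$temperature_celsius + 273.15
  q <- exp(-delta_g / (1.98720425864083e-3 * tk)) *
    conditions$initial_concentration_molar
  f <- function(y) q * (1 - y)^2 - y
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## Small deterministic glyph corpus shared by model tests (built once per
## test run; ~1.5 s).
tiny_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_glyph_dataset(30L, seed = 402L,
                                       n_test_per_class = 5L)
    }
    cache
  }
})
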