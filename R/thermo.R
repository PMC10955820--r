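## Built-in yield oracle: duplex free energy from nearest-neighbor stacks via
## an alignment-style dynamic program (src/duplex.cpp), then two-state
## mass-action equilibrium yield at the reaction conditions. A pluggable
## backend contract lets a full secondary-structure engine (e.g. a NUPACK
## adapter) replace the builtin model with the same call signature.

## kcal/(mol*K)
GAS_CONSTANT_KCAL <- 1.98720425864083e-3

.params_cache <- new.env(parent = emptyenv())

#' Load the bundled nearest-neighbor parameter table
#'
#' Parses the versioned plain-text table of Watson-Crick dinucleotide stack
#' enthalpies/entropies, the duplex initiation term, and the package's fixed
#' internal-mismatch and interior-loop penalties. Loading is deterministic
#' and validated: all 10 unique stacks must be present and every stack must
#' be stabilizing (negative free energy) at 37 degrees C.
#'
#' @param path Parameter file; defaults to the table bundled with the
#'   package.
#' @return An object of class `nn_params`.
#' @export
nn_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_unified_v1.txt", package = "hybriclass")
    if (!is.null(.params_cache$default)) return(.params_cache$default)
    default <- TRUE
  } else default <- FALSE

  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")

  stack_dH <- numeric(0)
  stack_dS <- numeric(0)
  init_dH <- init_dS <- NA_real_
  consts <- list()
  for (tk in toks) {
    if (tk[1L] == "stack") {
      stack_dH[tk[2L]] <- as.numeric(tk[3L])
      stack_dS[tk[2L]] <- as.numeric(tk[4L])
    } else if (tk[1L] == "init") {
      init_dH <- as.numeric(tk[2L])
      init_dS <- as.numeric(tk[3L])
    } else if (tk[1L] == "const") {
      consts[[tk[2L]]] <- as.numeric(tk[3L])
    } else stop(sprintf("unknown record type '%s' in %s", tk[1L], path),
                call. = FALSE)
  }

  wanted <- c("AA", "AT", "TA", "CA", "GT", "CT", "GA", "CG", "GC", "GG")
  if (!setequal(names(stack_dH), wanted)) {
    stop("parameter table must define exactly the 10 unique WC stacks",
         call. = FALSE)
  }
  dg37 <- stack_dH - 310.15 * stack_dS / 1000
  if (any(dg37 >= 0)) {
    stop("every WC stack must have negative free energy at 37 C",
         call. = FALSE)
  }
  if (anyNA(c(init_dH, init_dS))) stop("missing init record", call. = FALSE)
  for (nm in c("mismatch_penalty_dG", "loop_open_dG", "loop_extend_dG")) {
    if (is.null(consts[[nm]])) stop(sprintf("missing const %s", nm),
                                    call. = FALSE)
  }

  p <- structure(list(stack_dH = stack_dH[wanted], stack_dS = stack_dS[wanted],
                      init_dH = init_dH, init_dS = init_dS,
                      mismatch_penalty_dG = consts$mismatch_penalty_dG,
                      loop_open_dG = consts$loop_open_dG,
                      loop_extend_dG = consts$loop_extend_dG,
                      source = path),
                 class = "nn_params")
  if (default) .params_cache$default <- p
  p
}

## 4x4 stack dG matrix at temperature T (Celsius), indexed by the top-strand
## dinucleotide (first base = row, second = column; order A,T,C,G). The six
## unlisted dinucleotides take the value of their reverse complement.
stack_dg_matrix <- function(params, temperature_celsius) {
  tk <- temperature_celsius + 273.15
  dg10 <- params$stack_dH - tk * params$stack_dS / 1000
  m <- matrix(NA_real_, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  for (key in names(dg10)) {
    a <- substr(key, 1, 1); b <- substr(key, 2, 2)
    m[a, b] <- dg10[[key]]
    rc <- reverse_complement(key)
    m[substr(rc, 1, 1), substr(rc, 2, 2)] <- dg10[[key]]
  }
  stopifnot(!anyNA(m))
  m
}

#' Reaction conditions governing all yield computations
#'
#' @param temperature_celsius Hybridization temperature (default 25).
#' @param initial_concentration_molar Initial concentration of each strand
#'   (default 1e-9, i.e. 1 nM).
#' @param backend `"builtin_two_state"` (default) or `"external_adapter"`.
#' @param adapter For the external backend: a function
#'   `function(a, b, conditions)` returning a yield in `[0, 1]`.
#' @param params Nearest-neighbor table used by the builtin backend.
#' @return An object of class `hybridization_conditions`. The maximum complex
#'   size is fixed at 2 (pairwise duplexes only).
#' @export
hybridization_conditions <- function(temperature_celsius = 25,
                                     initial_concentration_molar = 1e-9,
                                     backend = c("builtin_two_state",
                                                 "external_adapter"),
                                     adapter = NULL,
                                     params = nn_params()) {
  backend <- match.arg(backend)
  if (temperature_celsius < 0 || temperature_celsius > 100) {
    stop("temperature must be within [0, 100] C", call. = FALSE)
  }
  if (initial_concentration_molar <= 0) {
    stop("initial concentration must be > 0", call. = FALSE)
  }
  if (!is.null(adapter) && !is.function(adapter)) {
    stop("adapter must be a function(a, b, conditions)", call. = FALSE)
  }
  structure(list(temperature_celsius = temperature_celsius,
                 initial_concentration_molar = initial_concentration_molar,
                 max_complex_size = 2L, backend = backend, adapter = adapter,
                 params = params),
            class = "hybridization_conditions")
}

#' @export
print.hybridization_conditions <- function(x, ...) {
  cat(sprintf(paste0("Hybridization conditions: %g C, %g M per strand, ",
                     "max complex size %d, backend '%s'\n"),
              x$temperature_celsius, x$initial_concentration_molar,
              x$max_complex_size, x$backend))
  invisible(x)
}

#' Minimum duplex free energy of two strands
#'
#' Minimum standard free energy (kcal/mol) over all duplex registrations of
#' `a` against `b` (both given 5'->3'), computed by an alignment-style
#' dynamic program: contiguous Watson-Crick dinucleotide stacks contribute
#' `dH - T*dS`, internal mismatches a fixed penalty, interior unpaired
#' stretches an affine loop penalty, plus one initiation term. Terminal
#' overhangs are free. Returns `Inf` (no binding) when the strands share no
#' complementary base pair or either is shorter than 2 nt.
#'
#' @param a,b DNA sequences (physical strands, 5'->3').
#' @param params Nearest-neighbor table, see [nn_params()].
#' @param temperature_celsius Temperature in `[0, 100]`.
#' @return Free energy in kcal/mol, or `Inf` for no binding.
#' @export
duplex_free_energy <- function(a, b, params = nn_params(),
                               temperature_celsius = 25) {
  validate_dna(a)
  validate_dna(b)
  if (temperature_celsius < 0 || temperature_celsius > 100) {
    stop("temperature must be within [0, 100] C", call. = FALSE)
  }
  if (nchar(a) < 2L || nchar(b) < 2L) return(Inf)
  sm <- stack_dg_matrix(params, temperature_celsius)
  tk <- temperature_celsius + 273.15
  .duplex_dg_cpp(a, reverse_complement(b), sm,
                 params$init_dH - tk * params$init_dS / 1000,
                 params$mismatch_penalty_dG, params$loop_open_dG,
                 params$loop_extend_dG)
}

#' Two-state equilibrium hybridization yield
#'
#' Solves the mass-action equilibrium `A + B <-> AB` with both strands at
#' initial concentration `c0` and `K = exp(-dG/RT) / c0_std` (standard state
#' 1 M). The yield -- the equilibrium duplex fraction, dsDNA concentration
#' over initial ssDNA concentration -- is the root in `[0, 1]` of
#' `K * c0 * (1 - y)^2 = y`, evaluated in the numerically stable closed form
#' `y = 2q / (2q + 1 + sqrt(4q + 1))` with `q = K * c0`.
#'
#' @param delta_g Free energy in kcal/mol (vectorized); `Inf` means no
#'   binding and yields 0.
#' @param conditions A [hybridization_conditions()] object.
#' @return Yield value(s) in `[0, 1]`.
#' @export
equilibrium_yield <- function(delta_g, conditions = hybridization_conditions()) {
  tk <- conditions$temperature_celsius + 273.15
  q <- exp(-delta_g / (GAS_CONSTANT_KCAL * tk)) *
    conditions$initial_concentration_molar
  y <- ifelse(is.finite(q), 2 * q / (2 * q + 1 + sqrt(4 * q + 1)), 1)
  y[is.infinite(delta_g) & delta_g > 0] <- 0
  y
}

#' Predict the hybridization yield of a strand pair
#'
#' The default (builtin) backend composes [duplex_free_energy()] with
#' [equilibrium_yield()]. `a` and `b` are the physical strands as given:
#' callers wanting the yield of a probe against an instance pass the probe
#' (e.g. a query's reverse complement) explicitly. The operation is
#' symmetric in its arguments.
#'
#' @param a,b DNA sequences (5'->3').
#' @param conditions A [hybridization_conditions()] object; its `backend`
#'   field selects the builtin two-state model or a registered external
#'   adapter.
#' @return Yield in `[0, 1]`.
#' @export
predict_yield <- function(a, b, conditions = hybridization_conditions()) {
  if (conditions$backend == "external_adapter") {
    if (is.null(conditions$adapter)) {
      stop("backend 'external_adapter' selected but no adapter registered",
           call. = FALSE)
    }
    return(conditions$adapter(a, b, conditions))
  }
  dg <- duplex_free_energy(a, b, conditions$params,
                           conditions$temperature_celsius)
  as.numeric(equilibrium_yield(dg, conditions))
}

## Elementwise yields for parallel vectors of strand pairs (builtin backend
## fast path; falls back to predict_yield under an external adapter).
yield_pairs <- function(a, b, conditions = hybridization_conditions()) {
  stopifnot(length(a) == length(b))
  if (conditions$backend == "external_adapter") {
    return(vapply(seq_along(a),
                  function(i) predict_yield(a[[i]], b[[i]], conditions),
                  numeric(1)))
  }
  params <- conditions$params
  tk <- conditions$temperature_celsius + 273.15
  sm <- stack_dg_matrix(params, conditions$temperature_celsius)
  dg <- .duplex_dg_pairs_cpp(as.character(a),
                             vapply(b, reverse_complement, character(1)),
                             sm, params$init_dH - tk * params$init_dS / 1000,
                             params$mismatch_penalty_dG, params$loop_open_dG,
                             params$loop_extend_dG)
  as.numeric(equilibrium_yield(dg, conditions))
}

#' Pairwise yield matrix
#'
#' Element `(i, j)` is `predict_yield(queries[i], targets[j])`; rows and
#' columns keep input order. The builtin backend evaluates the whole block in
#' compiled code.
#'
#' @param queries,targets Character vectors of DNA sequences.
#' @param conditions A [hybridization_conditions()] object.
#' @return A `length(queries)` x `length(targets)` numeric matrix of yields.
#' @export
yield_matrix <- function(queries, targets,
                         conditions = hybridization_conditions()) {
  if (!length(queries) || !length(targets)) {
    stop("queries and targets must be non-empty", call. = FALSE)
  }
  lapply(queries, validate_dna)
  lapply(targets, validate_dna)
  if (conditions$backend == "external_adapter") {
    if (is.null(conditions$adapter)) {
      stop("backend 'external_adapter' selected but no adapter registered",
           call. = FALSE)
    }
    out <- matrix(NA_real_, length(queries), length(targets))
    for (i in seq_along(queries)) {
      for (j in seq_along(targets)) {
        out[i, j] <- conditions$adapter(queries[[i]], targets[[j]], conditions)
      }
    }
    return(out)
  }
  params <- conditions$params
  tk <- conditions$temperature_celsius + 273.15
  sm <- stack_dg_matrix(params, conditions$temperature_celsius)
  dg <- .duplex_dg_matrix_cpp(as.character(queries),
                              vapply(targets, reverse_complement,
                                     character(1)),
                              sm, params$init_dH - tk * params$init_dS / 1000,
                              params$mismatch_penalty_dG, params$loop_open_dG,
                              params$loop_extend_dG)
  matrix(equilibrium_yield(dg, conditions), nrow = length(queries))
}
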