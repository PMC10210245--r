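# Atomic species and form factors.
#
# Elastic X-ray form factors use the standard four-Gaussian Cromer-Mann
# parameterization
#   f_A(q) = sum_i a_i exp(-b_i (q / 4 pi)^2) + c
# with q the momentum transfer in inverse Angstrom. Coefficients are the
# published International Tables values for neutral atoms; the
# parameterization reproduces f_A(0) = Z_A to better than 0.5%.
#
# Inelastic (incoherent) form factors S_A(q) are shipped as a sampled table
# per species with monotone cubic interpolation between nodes. The embedded
# table is generated from the closed form S_A(q) = Z_A (1 - (f_A(q)/Z_A)^2)
# (exact for one-electron atoms), which obeys S_A(0) = 0 and S_A -> Z_A as
# q -> infinity. The table source is pluggable should a different
# tabulation be preferred.

.cromer_mann <- list(
  H = list(Z = 1L,
           a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159),
           c = 0.001305),
  C = list(Z = 6L,
           a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512),
           c = 0.215600),
  N = list(Z = 7L,
           a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600),
           c = -11.529),
  O = list(Z = 8L,
           a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089),
           c = 0.250800),
  S = list(Z = 16L,
           a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720),
           c = 0.866900)
)

# q nodes for the embedded inelastic tables (inverse Angstrom)
.inelastic_q_nodes <- c(seq(0, 10, by = 0.25), seq(10.5, 25, by = 0.5),
                        seq(26, 60, by = 1))

.species_cache <- new.env(parent = emptyenv())

#' Supported chemical elements
#'
#' @return Character vector of element symbols with embedded form-factor
#'   parameterizations.
#' @export
supported_species <- function() names(.cromer_mann)

#' Atomic species descriptor
#'
#' Bundles the atomic number, the elastic form-factor parameterization and
#' the sampled inelastic scattering function for one element.
#'
#' @param symbol Element symbol (one of [supported_species()]).
#' @return An object of class `atomic_species` with fields `symbol`, `Z`,
#'   `elastic_coeffs` (Cromer-Mann `a`, `b`, `c`) and `inelastic_table`
#'   (`q`, `S` sample nodes).
#' @export
atomic_species <- function(symbol) {
  if (!is.character(symbol) || length(symbol) != 1L)
    stop("'symbol' must be a single element symbol", call. = FALSE)
  if (!symbol %in% names(.cromer_mann))
    stop(sprintf("unsupported species '%s' (supported: %s)", symbol,
                 paste(names(.cromer_mann), collapse = ", ")), call. = FALSE)
  if (!is.null(.species_cache[[symbol]])) return(.species_cache[[symbol]])
  cm <- .cromer_mann[[symbol]]
  qn <- .inelastic_q_nodes
  f <- .cm_eval(cm, qn)
  S <- cm$Z * (1 - (f / cm$Z)^2)
  S <- pmax(S, 0)
  S[qn == 0] <- 0  # exact: no incoherent scattering in the forward limit
  sp <- structure(list(symbol = symbol, Z = cm$Z, elastic_coeffs = cm,
                       inelastic_table = list(q = qn, S = S)),
                  class = "atomic_species")
  assign(symbol, sp, envir = .species_cache)
  sp
}

#' @export
print.atomic_species <- function(x, ...) {
  cat(sprintf("<atomic_species %s (Z = %d)>\n", x$symbol, x$Z))
  invisible(x)
}

.cm_eval <- function(cm, q) {
  s2 <- (q / (4 * pi))^2
  out <- rep(cm$c, length(q))
  for (i in seq_along(cm$a)) out <- out + cm$a[i] * exp(-cm$b[i] * s2)
  out
}

.as_species <- function(x) {
  if (inherits(x, "atomic_species")) x else atomic_species(x)
}

#' Probe kinds
#'
#' @return Character vector of recognised probe kinds.
#' @export
probe_kinds <- function() c("xray", "electron")

#' Elastic atomic form factor
#'
#' X-ray form factors come from the embedded Cromer-Mann parameterization.
#' Electron form factors are obtained through the Mott-Bethe conversion
#' `(Z - f_xray(q)) / q^2`; the `q -> 0` singularity is excluded by a hard
#' cutoff rather than regularized, since experimental s-grids never include
#' zero.
#'
#' @param species An `atomic_species` or an element symbol.
#' @param q Momentum transfer (inverse Angstrom), non-negative; for the
#'   electron probe all values must be at least `q_min_electron`.
#' @param probe `"xray"` or `"electron"`.
#' @param q_min_electron Lower cutoff for the electron probe (inverse
#'   Angstrom).
#' @return Numeric vector of scattering amplitudes, one per `q`.
#' @export
elastic_form_factor <- function(species, q, probe = "xray",
                                q_min_electron = 1e-3) {
  probe <- match.arg(probe, probe_kinds())
  sp <- .as_species(species)
  if (any(!is.finite(q)) || any(q < 0))
    stop("'q' must be finite and non-negative", call. = FALSE)
  fx <- .cm_eval(sp$elastic_coeffs, q)
  if (probe == "xray") return(fx)
  if (any(q < q_min_electron))
    stop(sprintf(paste0("electron form factor requested below the ",
                        "q_min_electron cutoff (%g 1/Angstrom); the q -> 0 ",
                        "singularity is excluded, not regularized"),
                 q_min_electron), call. = FALSE)
  (sp$Z - fx) / q^2
}

#' Inelastic atomic form factor
#'
#' Monotone cubic interpolation of the embedded per-species table; requests
#' outside the tabulated q-range are an error (no silent extrapolation).
#'
#' @inheritParams elastic_form_factor
#' @return Numeric vector `S_A(q)`.
#' @export
inelastic_form_factor <- function(species, q) {
  sp <- .as_species(species)
  tab <- sp$inelastic_table
  if (any(q < min(tab$q) - 1e-12) || any(q > max(tab$q) + 1e-12))
    stop(sprintf("q outside the inelastic table range [%g, %g] 1/Angstrom",
                 min(tab$q), max(tab$q)), call. = FALSE)
  fun <- stats::splinefun(tab$q, tab$S, method = "monoH.FC")
  pmax(fun(pmin(pmax(q, min(tab$q)), max(tab$q))), 0)
}

#' Total inelastic scattering of a composition
#'
#' Incoherent sum `sum_A S_A(q)` over the listed atoms; independent of
#' geometry.
#'
#' @param symbols Character vector of element symbols (one entry per atom,
#'   repeats allowed).
#' @param q Momentum transfer grid (inverse Angstrom).
#' @return Numeric vector, one value per `q`.
#' @export
inelastic_sum <- function(symbols, q) {
  out <- numeric(length(q))
  counts <- table(symbols)
  for (sym in names(counts))
    out <- out + as.numeric(counts[[sym]]) * inelastic_form_factor(sym, q)
  out
}
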