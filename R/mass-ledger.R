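# Elemental bookkeeping for peptides and the Thr -> Dmp pathway.
# Supported elements: H, C, N, O, S.

.ELEMENTS <- c("H", "C", "N", "O", "S")

.MONO_MASS <- c(H = 1.007825, C = 12.000000, N = 14.003074,
                O = 15.994915, S = 31.972071)
.AVG_MASS <- c(H = 1.00794, C = 12.0107, N = 14.0067,
               O = 15.9994, S = 32.065)
.NOMINAL_MASS <- c(H = 1L, C = 12L, N = 14L, O = 16L, S = 32L)
.PROTON_MASS <- 1.007276

# residue (dehydrated) elemental compositions of the 20 standard amino acids
.RESIDUE_FORMULA <- list(
  A = c(C = 3, H = 5, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  G = c(C = 2, H = 3, N = 1, O = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  K = c(C = 6, H = 12, N = 2, O = 1),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  P = c(C = 5, H = 7, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  T = c(C = 4, H = 7, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  V = c(C = 5, H = 9, N = 1, O = 1))

#' Construct a chemical formula
#'
#' @param ... Named element counts (H, C, N, O, S), e.g.
#'   `chemical_formula(H = 2, O = 1)` for water; or a single named vector.
#' @return Named integer vector over H, C, N, O, S of class `chem_formula`.
#' @export
chemical_formula <- function(...) {
  args <- list(...)
  counts <- if (length(args) == 1L && !is.null(names(args[[1L]]))) args[[1L]]
            else unlist(args)
  if (length(counts) && is.null(names(counts))) stop("element counts must be named")
  unknown <- setdiff(names(counts), .ELEMENTS)
  if (length(unknown)) stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  f <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  if (length(counts)) f[names(counts)] <- as.integer(round(counts))
  if (any(f < 0)) stop("element counts must be nonnegative")
  structure(f, class = "chem_formula")
}

#' @export
print.chem_formula <- function(x, ...) {
  nz <- x[x != 0]
  if (!length(nz)) cat("(empty formula)\n")
  else cat(paste0(names(nz), ifelse(nz == 1, "", nz), collapse = ""), "\n")
  invisible(x)
}

#' Elemental formula of a linear peptide
#'
#' Sum of residue compositions plus one water (the free termini). The empty
#' chain returns H2O by convention.
#'
#' @param seq Peptide string over the 20 standard amino acids.
#' @return A `chem_formula`.
#' @examples
#' peptide_formula("G")   # free glycine, C2H5NO2
#' @export
peptide_formula <- function(seq) {
  aas <- strsplit(toupper(seq), "")[[1L]]
  bad <- setdiff(aas, names(.RESIDUE_FORMULA))
  if (length(bad)) stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  f <- stats::setNames(numeric(length(.ELEMENTS)), .ELEMENTS)
  for (aa in aas) {
    r <- .RESIDUE_FORMULA[[aa]]
    f[names(r)] <- f[names(r)] + r
  }
  f[["H"]] <- f[["H"]] + 2
  f[["O"]] <- f[["O"]] + 1
  chemical_formula(f)
}

# per-step elemental deltas of the daptide pathway and derivatizations
.MOD_DELTAS <- list(
  oxidative_decarboxylation = c(C = -1, H = -2, O = -2),  # Thr -> C-terminal methyl ketone, -46 nominal
  transamination            = c(N = 1, H = 3, O = -1),    # ketone -> primary amine, +1 vs ketone
  dimethylation             = c(C = 2, H = 4),            # amine -> N,N-dimethyl (Dmp), +28
  ser_to_ala                = c(O = -1),                  # dehydration/reduction of Ser, per site
  benzyl_oxime              = c(C = 7, H = 7, N = 1))     # ketone + O-benzylhydroxylamine - H2O, +105

#' Modification steps of the daptide mass ledger
#'
#' @return Character vector of recognized step names.
#' @export
modification_steps <- function() names(.MOD_DELTAS)

#' Elemental delta of a single modification step
#'
#' @param step One of [modification_steps()].
#' @return Named integer vector (signed element counts).
#' @export
step_delta <- function(step) {
  if (!step %in% names(.MOD_DELTAS)) stop("unknown step: ", step)
  d <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  d[names(.MOD_DELTAS[[step]])] <- .MOD_DELTAS[[step]]
  d
}

# validate pathway ordering; `sequence` (optional) enables site checks
.check_steps <- function(steps, sites, sequence = NULL) {
  unknown <- setdiff(steps, names(.MOD_DELTAS))
  if (length(unknown)) stop("unknown step(s): ", paste(unknown, collapse = ", "))
  seen <- character()
  for (s in steps) {
    if (s == "transamination" && !"oxidative_decarboxylation" %in% seen)
      stop("transamination requires prior oxidative_decarboxylation")
    if (s == "dimethylation" && !"transamination" %in% seen)
      stop("dimethylation requires prior transamination")
    if (s == "benzyl_oxime" &&
        (!"oxidative_decarboxylation" %in% seen || "transamination" %in% seen))
      stop("benzyl_oxime requires the ketone state (after oxidative decarboxylation, before transamination)")
    seen <- c(seen, s)
  }
  if (!is.null(sequence)) {
    if ("oxidative_decarboxylation" %in% steps &&
        substring(sequence, nchar(sequence), nchar(sequence)) != "T")
      stop("oxidative_decarboxylation requires a C-terminal Thr")
    n_ser <- lengths(regmatches(sequence, gregexpr("S", sequence)))
    k <- if ("ser_to_ala" %in% names(sites)) sites[["ser_to_ala"]] else 0L
    if (k > n_ser) stop("ser_to_ala site count (", k, ") exceeds Ser residues (", n_ser, ")")
  }
  invisible(TRUE)
}

#' Apply an ordered list of modification steps to a formula
#'
#' Deltas are applied element-wise in order; `ser_to_ala` is multiplied by
#' its site count. Ordering constraints of the pathway are enforced
#' (transamination after oxidative decarboxylation, dimethylation after
#' transamination, oxime formation only on the ketone state). If `sequence`
#' is supplied, the C-terminal-Thr and Ser-count site requirements are also
#' checked.
#'
#' @param formula A `chem_formula` (e.g. from [peptide_formula()]).
#' @param steps Character vector of step names, in order.
#' @param sites Named integer vector of site counts (only `ser_to_ala`
#'   is site-multiplied), e.g. `c(ser_to_ala = 5)`.
#' @param sequence Optional peptide string for site-requirement checks.
#' @return The modified `chem_formula`.
#' @export
apply_steps <- function(formula, steps = character(), sites = c(ser_to_ala = 0L),
                        sequence = NULL) {
  .check_steps(steps, sites, sequence)
  f <- as.numeric(formula)
  names(f) <- names(formula)
  for (s in steps) {
    mult <- if (s == "ser_to_ala") {
      if (!"ser_to_ala" %in% names(sites)) 1L else as.integer(sites[["ser_to_ala"]])
    } else 1L
    f <- f + step_delta(s) * mult
    if (any(f < 0)) stop("step '", s, "' drives an element count negative")
  }
  chemical_formula(f)
}

#' Mass of a chemical formula
#'
#' Nominal mass is the sum over integer element masses (H 1, C 12, N 14,
#' O 16, S 32), not a rounding of the monoisotopic mass — matching the
#' integer "Da lighter" bookkeeping of the pathway.
#'
#' @param formula A `chem_formula`.
#' @param kind One of "monoisotopic", "average", "nominal".
#' @return Numeric (integer for nominal) mass in Da.
#' @export
formula_mass <- function(formula, kind = c("monoisotopic", "average", "nominal")) {
  kind <- match.arg(kind)
  tab <- switch(kind, monoisotopic = .MONO_MASS, average = .AVG_MASS,
                nominal = .NOMINAL_MASS)
  m <- sum(as.numeric(formula) * tab[names(formula)])
  if (kind == "nominal") as.integer(round(m)) else m
}

#' Net nominal mass change of a modification pathway
#'
#' @param steps Ordered step names.
#' @param sites Site counts (see [apply_steps()]).
#' @return Integer Da, sign preserved (the full Thr -> Dmp pathway gives -17).
#' @examples
#' delta_nominal("oxidative_decarboxylation")                     # -46
#' delta_nominal(c("oxidative_decarboxylation", "transamination")) # -45
#' @export
delta_nominal <- function(steps, sites = c(ser_to_ala = 0L)) {
  .check_steps(steps, sites)
  d <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  for (s in steps) {
    mult <- if (s == "ser_to_ala") as.integer(sites[["ser_to_ala"]]) else 1L
    d <- d + step_delta(s) * mult
  }
  as.integer(sum(d * .NOMINAL_MASS[names(d)]))
}

#' Singly protonated m/z of a formula
#'
#' \[M+H\]+ convention (MALDI context): monoisotopic mass plus the proton
#' mass (1.007276 Da). Only charge 1 is supported.
#'
#' @param formula A `chem_formula`.
#' @param charge Must be 1.
#' @return m/z in Th.
#' @export
protonated_mz <- function(formula, charge = 1L) {
  if (charge != 1L) stop("only singly protonated species are supported")
  formula_mass(formula, "monoisotopic") + .PROTON_MASS
}

# enumerate modification states of a peptide: base pathway states crossed
# with 0..n_ser Ser->Ala conversions
.enumerate_states <- function(peptide) {
  n_ser <- lengths(regmatches(peptide, gregexpr("S", peptide)))
  ends_thr <- substring(peptide, nchar(peptide), nchar(peptide)) == "T"
  base <- list(unmodified = character())
  if (ends_thr) {
    base$ketone <- "oxidative_decarboxylation"
    base$oxime <- c("oxidative_decarboxylation", "benzyl_oxime")
    base$amine <- c("oxidative_decarboxylation", "transamination")
    base$Dmp <- c("oxidative_decarboxylation", "transamination", "dimethylation")
  }
  states <- list()
  for (nm in names(base)) {
    for (k in 0:n_ser) {
      label <- if (k == 0L) nm else paste0(nm, "+", k, "xSer->Ala")
      states[[label]] <- list(steps = c(base[[nm]],
                                        if (k > 0L) "ser_to_ala"),
                              sites = c(ser_to_ala = k))
    }
  }
  states
}

#' Match an observed m/z to a modification state
#'
#' Enumerates the modification states of a peptide (unmodified, ketone,
#' amine, Dmp, benzyl oxime, each combined with 0..n Ser->Ala conversions),
#' computes each state's protonated m/z, and returns the states within
#' `tolerance` of the observation, ranked by absolute error.
#'
#' @param observed_mz Observed singly protonated m/z (Da).
#' @param peptide Core or precursor peptide string.
#' @param tolerance Matching tolerance in Da (> 0).
#' @return Data.frame: `state`, `mz`, `error` (observed - state), ordered by
#'   `abs(error)`; zero rows if nothing is within tolerance.
#' @export
match_intermediate <- function(observed_mz, peptide, tolerance = 1.0) {
  stopifnot(tolerance > 0)
  f0 <- peptide_formula(peptide)
  states <- .enumerate_states(peptide)
  mz <- vapply(states, function(st)
    protonated_mz(apply_steps(f0, st$steps, st$sites, sequence = peptide)), 0)
  err <- observed_mz - mz
  hit <- abs(err) <= tolerance
  out <- data.frame(state = names(states)[hit], mz = mz[hit], error = err[hit],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(abs(out$error)), , drop = FALSE]
}
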