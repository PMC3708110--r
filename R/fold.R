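#' RNA secondary structure folding
#'
#' The built-in folder finds the minimum-free-energy nested secondary
#' structure of a short RNA under a simplified stacking energy model:
#' the energy of a structure is a sum over its base pairs, where a pair
#' closing an empty interior (a hairpin loop, at least 3 unpaired bases)
#' pays the hairpin initiation penalty, a pair stacked directly on another
#' pair gains the mean of the two pair strengths (GC 3.4, AU 2.2, GU 1.4
#' kcal/mol), and a pair enclosing a non-stacked structured interior pays
#' the internal-loop penalty (see [fold_params()] for the calibrated
#' values). The model keeps the qualitative behaviour of nearest-neighbor
#' thermodynamics (long stacked helices are strongly stabilising, isolated
#' pairs are not) while remaining simple enough that an exhaustive
#' enumeration oracle can certify optimality on short sequences.
#'
#' @param sequence RNA or DNA string (ACGU/ACGT); folded as RNA.
#' @param params Energy parameters, see [fold_params()].
#' @return A `hairpin_fold` list: `sequence` (RNA alphabet), `dot_bracket`,
#'   `mfe` (kcal/mol, <= 0), `pairs` (integer vector, 1-based partner or 0),
#'   `n_hairpin_loops`.
#' @export
fold_hairpin <- function(sequence, params = fold_params()) {
  rna <- gsub("T", "U", toupper(sequence))
  if (grepl("[^ACGU]", rna)) stop("sequence contains non-ACGU characters")
  res <- .fold_mfe_cpp(rna, params$hairpin_penalty, params$internal_penalty)
  pairs <- res$pairs
  db <- rep(".", nchar(rna))
  db[pairs > seq_along(pairs)] <- "("
  db[pairs > 0 & pairs < seq_along(pairs)] <- ")"
  structure(list(sequence = rna,
                 dot_bracket = paste(db, collapse = ""),
                 mfe = res$mfe,
                 pairs = pairs,
                 n_hairpin_loops = count_hairpin_loops(pairs)),
            class = "hairpin_fold")
}

#' @export
print.hairpin_fold <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, "\n",
      sprintf("mfe = %.1f kcal/mol, %d hairpin loop(s)\n",
              x$mfe, x$n_hairpin_loops), sep = "")
  invisible(x)
}

# number of pairs with no pair anywhere in their interior
count_hairpin_loops <- function(pairs) {
  idx <- which(pairs > seq_along(pairs))
  if (!length(idx)) return(0L)
  sum(vapply(idx, function(i) {
    j <- pairs[i]
    inner <- seq(i + 1L, j - 1L)
    all(pairs[inner] == 0L)
  }, logical(1)))
}

#' Energy of an explicit secondary structure
#'
#' Evaluates the folding energy model directly on a structure given as a
#' set of pairs; this is the defining form of the model and the quantity
#' the folding dynamic program minimises. Used by the exhaustive-enumeration
#' oracle that certifies [fold_hairpin()].
#'
#' @param sequence RNA string.
#' @param pairs Two-column integer matrix of 1-based pair positions (i < j),
#'   or an integer partner vector as returned by [fold_hairpin()].
#' @param params Energy parameters, see [fold_params()].
#' @return Energy in kcal/mol.
#' @export
structure_energy <- function(sequence, pairs, params = fold_params()) {
  rna <- gsub("T", "U", toupper(sequence))
  b <- strsplit(rna, "")[[1]]
  if (is.matrix(pairs)) {
    pv <- integer(length(b))
    if (nrow(pairs)) { pv[pairs[, 1]] <- pairs[, 2]; pv[pairs[, 2]] <- pairs[, 1] }
  } else pv <- pairs
  idx <- which(pv > seq_along(pv))
  strength <- function(a, c) {
    k <- paste0(a, c)
    switch(k, GC = , CG = 3.4, AU = , UA = 2.2, GU = , UG = 1.4, 0)
  }
  e <- 0
  for (i in idx) {
    j <- pv[i]
    inner <- if (j - i >= 2L) seq(i + 1L, j - 1L) else integer(0)
    if (all(pv[inner] == 0L)) {
      e <- e + params$hairpin_penalty    # hairpin loop
    } else if (pv[i + 1L] == j - 1L) {
      e <- e - (strength(b[i], b[j]) + strength(b[i + 1L], b[j - 1L])) / 2  # stack
    } else {
      e <- e + params$internal_penalty   # internal/branch
    }
  }
  e
}

#' Exhaustive-enumeration folding oracle
#'
#' Enumerates every legal nested structure (AU/GC/GU pairs, minimum loop 3)
#' of a short sequence and returns the minimum of [structure_energy()] over
#' all of them. Exponential: intended for sequences up to ~25 nt, where it
#' certifies that the dynamic program attains the optimum.
#'
#' @param sequence RNA/DNA string, length <= 30 enforced.
#' @param params Energy parameters, see [fold_params()].
#' @return Minimum energy (kcal/mol, <= 0 since the empty structure scores 0).
#' @export
fold_oracle_mfe <- function(sequence, params = fold_params()) {
  rna <- gsub("T", "U", toupper(sequence))
  n <- nchar(rna)
  if (n > 30L) stop("oracle is exhaustive; use sequences <= 30 nt")
  b <- strsplit(rna, "")[[1]]
  ok <- function(i, j) {
    k <- paste0(b[i], b[j])
    k %in% c("GC", "CG", "AU", "UA", "GU", "UG")
  }
  structures <- list()
  # enumerate nested pair sets over [i..j]; returns list of 2-col matrices
  memo <- new.env(hash = TRUE)
  enum <- function(i, j) {
    if (j - i < 4L) return(list(matrix(integer(0), ncol = 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- enum(i + 1L, j)           # i unpaired
    for (k in seq(i + 4L, j)) {
      if (!ok(i, k)) next
      ins <- enum(i + 1L, k - 1L)
      outs <- enum(k + 1L, j)
      for (a in ins) for (z in outs)
        out[[length(out) + 1L]] <- rbind(cbind(i, k), a, z)
    }
    memo[[key]] <- out
    out
  }
  all_s <- enum(1L, n)
  min(vapply(all_s, function(p) structure_energy(rna, p, params), numeric(1)))
}

#' Fraction of a subinterval's bases that are paired
#'
#' Used to score how tightly a candidate mature miRNA binds into one arm of
#' a folded hairpin.
#'
#' @param fold A `hairpin_fold`.
#' @param start,end 0-based half-open interval within the folded sequence.
#' @return Fraction in \[0, 1\].
#' @export
pairing_fraction <- function(fold, start, end) {
  idx <- seq(start + 1L, end)
  mean(fold$pairs[idx] > 0L)
}

#' Does an interval sit on a single arm of the fold?
#'
#' TRUE when the interval does not span the apex of any hairpin loop, i.e.
#' the mature candidate lies wholly on one side of the stem.
#'
#' @inheritParams pairing_fraction
#' @export
on_single_arm <- function(fold, start, end) {
  pairs <- fold$pairs
  idx <- which(pairs > seq_along(pairs))
  if (!length(idx)) return(FALSE)
  for (i in idx) {
    j <- pairs[i]
    inner <- seq(i + 1L, j - 1L)
    if (all(pairs[inner] == 0L)) {
      # hairpin loop occupies (i, j) exclusive; interval must not contain it
      if (start + 1L <= i && end >= j) return(FALSE)
    }
  }
  # partners of the interval's paired bases must lie outside the interval
  sub <- seq(start + 1L, end)
  partners <- pairs[sub]
  !any(partners %in% sub & partners > 0L)
}

#' Folding energy parameters
#'
#' Constants of the simplified stacking model: pair strengths (GC 3.4,
#' AU 2.2, GU 1.4 kcal/mol, averaged over the two pairs of each stack),
#' the hairpin-loop initiation penalty and the internal-loop/branch
#' penalty. The penalties were calibrated so that minimum free energies
#' track the nearest-neighbor thermodynamic scale on both canonical
#' pre-miRNA stem-loops and random sequence, keeping the conventional
#' -25 kcal/mol stability threshold meaningful.
#'
#' @param hairpin_penalty Cost of closing a hairpin loop (kcal/mol).
#' @param internal_penalty Cost of a pair enclosing non-stacked structure.
#' @export
fold_params <- function(hairpin_penalty = 6.5, internal_penalty = 6.5) {
  list(hairpin_penalty = hairpin_penalty, internal_penalty = internal_penalty)
}
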