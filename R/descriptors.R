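# Atomic van der Waals volume contributions (A^3) for the
# bond/ring-corrected additive volume approximation
# V = sum(atoms) - 5.92*N_bonds - 14.7*R_aromatic - 3.8*R_nonaromatic.
.VDW_CONTRIB <- c(H = 7.24, C = 20.58, N = 15.6, O = 14.71, F = 13.31,
                  Cl = 22.45, Br = 26.52, I = 32.52, P = 24.43, S = 24.43,
                  As = 26.52, B = 40.48, Si = 38.79, Se = 28.73, Te = 36.62)

.count_h_from_formula <- function(formula) {
  m <- regmatches(formula, regexec("H([0-9]*)", formula))[[1]]
  if (length(m) < 2 || !nzchar(m[1])) return(0L)
  if (!nzchar(m[2])) 1L else as.integer(m[2])
}

#' Compute the ten substituent descriptors from structures
#'
#' Convenience wrapper computing the descriptor vocabulary (see
#' [descriptor_names()]) for substituent fragments given as SMILES,
#' using the ChemmineR / ChemmineOB (OpenBabel) toolkits: logp, tpsa,
#' mw, acc (H-bond acceptors), don (H-bond donors) from OpenBabel;
#' ring counts from the heavy-atom graph (cyclomatic number; aromatic
#' rings by ring perception on rings of size <= 7); rotatable bonds as
#' acyclic single bonds between two non-terminal heavy atoms; and a
#' bond/ring-corrected additive van der Waals volume. Toolkit-derived
#' values (logp, tpsa, acc, don) are not bit-stable across toolkit
#' releases.
#'
#' @param smiles Character vector of parseable SMILES strings.
#' @return A data.frame with one row per structure and the ten
#'   descriptor columns.
#' @export
compute_substituent_descriptors <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE))
    stop("ChemmineR and ChemmineOB are required for descriptor computation")
  stopifnot(is.character(smiles), length(smiles) > 0)
  rows <- lapply(smiles, function(s) {
    sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(s))[[1]],
                    error = function(e) NULL)
    if (is.null(sdf)) stop("unparseable structure: ", s)
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    # a bond-free molecule gets a malformed 2-column placeholder block
    if (is.null(bb) || ncol(bb) < 3) bb <- NULL
    if (!is.null(bb)) storage.mode(bb) <- "integer"
    n_heavy <- nrow(ab)
    n_bonds_heavy <- if (is.null(bb)) 0L else nrow(bb)
    elements <- gsub("_.*$", "", rownames(ab))

    prop <- ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", s, identity))
    n_h <- .count_h_from_formula(prop$formula[1])

    # ring counts from the cyclomatic number of the heavy-atom graph
    comp <- .n_components(n_heavy, bb)
    n_rings <- n_bonds_heavy - n_heavy + comp
    n_arings <- 0L
    n_nonarom <- n_rings
    if (n_rings > 0) {
      rr <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                     error = function(e) NULL)
      if (!is.null(rr)) {
        small <- vapply(rr$RINGS, length, integer(1)) <= 7L
        n_arings <- sum(rr$AROMATIC[small])
        n_nonarom <- max(n_rings - n_arings, 0L)
      }
    }

    # rotatable bonds: acyclic single bonds joining non-terminal atoms
    rbc <- 0L
    if (!is.null(bb) && n_bonds_heavy > 0) {
      deg <- tabulate(c(bb[, 1], bb[, 2]), nbins = n_heavy)
      ring_bond <- .ring_bonds(n_heavy, bb)
      rbc <- sum(bb[, 3] == 1 & !ring_bond &
                   deg[bb[, 1]] > 1 & deg[bb[, 2]] > 1)
    }

    contrib <- .VDW_CONTRIB[elements]
    contrib[is.na(contrib)] <- 20.58  # fall back to carbon-sized
    vdw <- sum(contrib) + n_h * .VDW_CONTRIB[["H"]] -
      5.92 * (n_bonds_heavy + n_h) - 14.7 * n_arings - 3.8 * n_nonarom

    data.frame(arings = n_arings, acc = as.numeric(prop$HBA2[1]),
               don = as.numeric(prop$HBD[1]), a_heavy = n_heavy,
               logp = as.numeric(prop$logP[1]), rbc = rbc,
               rings = n_rings, tpsa = as.numeric(prop$TPSA[1]),
               vdw_vol = vdw, mw = as.numeric(prop$MW[1]))
  })
  do.call(rbind, rows)
}

.n_components <- function(n, bb) {
  if (n == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (!is.null(bb) && nrow(bb) > 0)
    for (k in seq_len(nrow(bb))) {
      a <- find(bb[k, 1]); b <- find(bb[k, 2])
      if (a != b) parent[a] <- b
    }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# a bond is in a ring iff removing it keeps its endpoints connected
.ring_bonds <- function(n, bb) {
  m <- nrow(bb)
  vapply(seq_len(m), function(k) {
    adj <- bb[-k, , drop = FALSE]
    reach <- rep(FALSE, n); reach[bb[k, 1]] <- TRUE
    repeat {
      hit <- adj[, 1] %in% which(reach) | adj[, 2] %in% which(reach)
      nxt <- unique(c(adj[hit, 1], adj[hit, 2]))
      if (all(reach[nxt])) break
      reach[nxt] <- TRUE
    }
    reach[bb[k, 2]]
  }, logical(1))
}
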