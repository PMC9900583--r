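# Covalent bond perception and peptide backbone annotation.

#' Perceive covalent bonds from interatomic distances
#'
#' Atoms i and j are bonded iff their distance does not exceed
#' `scale * (r_cov(i) + r_cov(j))`. The default scale 1.15 is the common
#' heuristic; only ring-order topology depends on it, not any energetics.
#'
#' @param s a `mol_structure`
#' @param scale unitless multiplier on the covalent-radius sum
#' @return the structure with its `bonds` field populated (i < j rows)
#' @export
perceive_bonds <- function(s, scale = 1.15) {
  n <- n_atoms(s)
  if (n < 2L) { s$bonds <- matrix(integer(0), ncol = 2L); return(s) }
  d <- as.matrix(stats::dist(s$coords))
  too_close <- d < 0.4 & upper.tri(d)
  if (any(too_close)) {
    ij <- which(too_close, arr.ind = TRUE)[1L, ]
    stop(sprintf("overlapping atoms %d and %d (distance %.3f A < 0.4 A)",
                 ij[1L], ij[2L], d[ij[1L], ij[2L]]))
  }
  r <- covalent_radius(s$elements)
  cutoff <- scale * outer(r, r, `+`)
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  s$bonds <- matrix(as.integer(hit[order(hit[, 1L], hit[, 2L]), ,
                                   drop = FALSE]), ncol = 2L)
  colnames(s$bonds) <- NULL
  s
}

# adjacency list from the bond table
bond_adjacency <- function(s) {
  n <- n_atoms(s)
  adj <- vector("list", n)
  for (r in seq_len(nrow(s$bonds))) {
    i <- s$bonds[r, 1L]; j <- s$bonds[r, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# BFS shortest path (atom indices, inclusive) on the covalent graph;
# NULL when disconnected
covalent_path <- function(s, from, to) {
  adj <- bond_adjacency(s)
  n <- n_atoms(s)
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  queue <- from; seen[from] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    if (v == to) {
      path <- v
      while (!is.na(prev[v])) { v <- prev[v]; path <- c(v, path) }
      return(path)
    }
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE; prev[w] <- v; queue <- c(queue, w)
    }
  }
  NULL
}

#' Annotate the peptide backbone of a linear peptide
#'
#' Walks the covalent graph from the free N-terminal amine to the COOH
#' C-terminus, assigning per-residue backbone atoms: amide N, C-alpha,
#' carbonyl C and O, the amide H (residues 2..n), and the side-chain
#' C-beta where present. Terminal groups (NH2 hydrogens; COOH carbonyl O,
#' hydroxyl O and its H) are recorded separately.
#'
#' @param s a `mol_structure` with bonds perceived
#' @return an object of class `backbone_annotation`: a list with
#'   `residues` (data.frame of atom indices: N, CA, C, O, H_amide, CB),
#'   `nterm` (N index, amine H indices) and `cterm` (C, O_carbonyl,
#'   O_hydroxyl, H_hydroxyl indices)
#' @export
annotate_backbone <- function(s) {
  if (nrow(s$bonds) == 0L) stop("perceive bonds before annotating a backbone")
  adj <- bond_adjacency(s)
  el <- s$elements
  nbrs <- function(i, elem = NULL) {
    v <- adj[[i]]
    if (is.null(elem)) v else v[el[v] == elem]
  }
  # N-terminal amine: N bonded to exactly two H and one C (the C-alpha)
  n_candidates <- which(el == "N" & vapply(seq_along(el), function(i) {
    length(nbrs(i, "H")) == 2L && length(nbrs(i, "C")) == 1L
  }, logical(1)))
  # COOH carbon: C bonded to two O, one of which carries an H
  cooh_candidates <- which(el == "C" & vapply(seq_along(el), function(i) {
    os <- nbrs(i, "O")
    length(os) == 2L && any(vapply(os, function(o)
      length(nbrs(o, "H")) == 1L, logical(1)))
  }, logical(1)))
  if (length(n_candidates) == 0L) {
    stop("structure is not a free peptide: no N-terminal amine (N with two H)")
  }
  if (length(cooh_candidates) == 0L) {
    stop("structure is not a free peptide: no COOH terminus found")
  }
  nterm_N <- n_candidates[1L]
  residues <- list()
  cur_N <- nterm_N
  prev_C <- NA_integer_
  repeat {
    ca_cands <- setdiff(nbrs(cur_N, "C"), prev_C)
    # C-alpha: carbon bonded to this N and to a carbonyl/COOH carbon
    ca <- NA_integer_; cc <- NA_integer_
    for (c1 in ca_cands) {
      for (c2 in setdiff(nbrs(c1, "C"), NA)) {
        os <- nbrs(c2, "O")
        if (length(os) >= 1L) { ca <- c1; cc <- c2; break }
      }
      if (!is.na(ca)) break
    }
    if (is.na(ca)) stop("backbone walk failed at atom ", cur_N,
                        ": no C-alpha/carbonyl pair")
    os <- nbrs(cc, "O")
    is_cooh <- cc %in% cooh_candidates
    if (is_cooh) {
      o_h <- os[vapply(os, function(o) length(nbrs(o, "H")) == 1L,
                       logical(1))][1L]
      o_carb <- setdiff(os, o_h)[1L]
    } else {
      o_carb <- os[which.max(vapply(os, function(o) length(adj[[o]]) == 1L,
                                    logical(1)))]
    }
    h_amide <- if (identical(cur_N, nterm_N)) NA_integer_ else {
      h <- nbrs(cur_N, "H"); if (length(h) >= 1L) h[1L] else NA_integer_
    }
    cb <- setdiff(nbrs(ca, "C"), cc)
    residues[[length(residues) + 1L]] <- data.frame(
      N = cur_N, CA = ca, C = cc, O = o_carb, H_amide = h_amide,
      CB = if (length(cb) >= 1L) cb[1L] else NA_integer_)
    if (is_cooh) {
      cterm <- list(C = cc, O_carbonyl = o_carb, O_hydroxyl = o_h,
                    H_hydroxyl = nbrs(o_h, "H")[1L])
      break
    }
    nxt <- setdiff(nbrs(cc, "N"), cur_N)
    if (length(nxt) == 0L) {
      stop("structure is not a free peptide: chain ends without a COOH")
    }
    prev_C <- cc
    cur_N <- nxt[1L]
  }
  res <- do.call(rbind, residues)
  rownames(res) <- NULL
  structure(
    list(residues = res,
         nterm = list(N = nterm_N, H = nbrs(nterm_N, "H")),
         cterm = cterm),
    class = "backbone_annotation"
  )
}

#' @export
print.backbone_annotation <- function(x, ...) {
  cat("Peptide backbone:", nrow(x$residues), "residues\n")
  invisible(x)
}

#' Number of residues in a backbone annotation
#' @param bb a `backbone_annotation`
#' @return integer residue count
#' @export
n_residues <- function(bb) nrow(bb$residues)
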