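# Conformer records: Gibbs-energy ranking, short names and Boltzmann
# abundances.

#' Construct a conformer set
#'
#' @param structures list of `mol_structure` objects (may be NULL entries
#'   when only energies are known)
#' @param gibbs numeric Gibbs energies, kcal/mol, at a common temperature
#' @param names optional character names; defaults filled in by
#'   [rank_and_weight()]
#' @return an object of class `conformer_set` (data.frame-backed)
#' @export
conformer_set <- function(structures = NULL, gibbs, names = NULL) {
  m <- length(gibbs)
  if (m == 0L) stop("a conformer set needs at least one conformer")
  if (is.null(structures)) structures <- vector("list", m)
  if (length(structures) != m) {
    stop("structures and gibbs must have equal length")
  }
  structure(
    list(structures = structures, gibbs = as.numeric(gibbs),
         name = names, short_name = rep(NA_character_, m),
         rank = rep(NA_integer_, m), abundance = rep(NA_real_, m)),
    class = "conformer_set"
  )
}

#' Number of conformers in a set
#' @param x a `conformer_set`
#' @return integer
#' @export
n_conformers <- function(x) length(x$gibbs)

#' @export
print.conformer_set <- function(x, ...) {
  cat("Conformer set:", n_conformers(x), "conformers\n")
  d <- as.data.frame(x)
  print(utils::head(d[order(d$gibbs), ], 10L), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.conformer_set <- function(x, ...) {
  data.frame(name = if (is.null(x$name)) x$short_name else x$name,
             short_name = x$short_name, gibbs = x$gibbs, rank = x$rank,
             abundance = x$abundance)
}

#' Rank conformers by Gibbs energy and assign Boltzmann abundances
#'
#' Abundances are Boltzmann weights
#' `exp(-G_i / kT) / sum_j exp(-G_j / kT)` with the minimum energy
#' subtracted before exponentiation for numerical stability. Ranks are
#' assigned by ascending Gibbs energy (ties broken by input order) and
#' short names are `"A<rank>"`.
#'
#' @param records a `conformer_set`
#' @param temperature temperature in K (default 400, the laser-desorption
#'   estimate)
#' @return the `conformer_set` with `rank`, `short_name` and `abundance`
#'   filled in
#' @export
rank_and_weight <- function(records, temperature = 400) {
  g <- records$gibbs
  if (length(g) == 0L) stop("empty conformer set")
  if (temperature <= 0) stop("temperature must be positive")
  kt <- phys_const$kB_kcal_mol * temperature
  w <- exp(-(g - min(g)) / kt)
  records$abundance <- w / sum(w)
  ord <- order(g)
  records$rank <- integer(length(g))
  records$rank[ord] <- seq_along(g)
  records$short_name <- paste0("A", records$rank)
  records
}
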