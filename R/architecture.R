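# Domain architecture of the pulled construct: residue partitions, disulfide
# clamps, linkers, and predicted unfolding lengths.

#' Load a protein domain-architecture table
#'
#' Reads a tab-separated architecture description with one row per domain and
#' columns `name`, `dclass` (`IgC2` or `FnIII`), `n_res` (total residues),
#' `n_protected` (residues clamped inside the disulfide bridge; 0 for FnIII),
#' `linker_after` (free residues to the next module) and `d_fold` (folded
#' N-to-C span in nm). Lines starting with `#` are comments.
#'
#' The packaged default describes the CNTN4 ectodomain: six N-terminal IgC2
#' modules, each restrained by one disulfide bond that shelters roughly half
#' of the domain from extension, followed by four FnIII modules that unfold
#' fully.
#'
#' @param path Path to the TSV file. Defaults to the packaged CNTN4 table.
#' @param l_aa Contour-length gain per unfolded residue (nm/aa); conventional
#'   values for polypeptide are 0.36-0.40 nm.
#' @return An object of class `protein_architecture`: list with `domains`
#'   (data.frame) and `l_aa`.
#' @export
load_architecture <- function(path = system.file("extdata", "cntn4_architecture.tsv",
                                                 package = "afmunfold"),
                              l_aa = 0.38) {
  if (!is.character(path) || length(path) != 1L || !nzchar(path) || !file.exists(path))
    stop("architecture config not found: ", path)
  if (!is.numeric(l_aa) || length(l_aa) != 1L || l_aa <= 0 || l_aa >= 1)
    stop("'l_aa' must be in (0, 1) nm per residue")
  d <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed architecture file: ", conditionMessage(e)))
  if (nrow(d) == 0L) stop("architecture file contains no domain rows")
  need <- c("name", "dclass", "n_res", "n_protected", "linker_after", "d_fold")
  if (!all(need %in% names(d)))
    stop("architecture file must have columns: ", paste(need, collapse = ", "))
  for (i in seq_len(nrow(d))) {
    r <- d[i, ]
    if (!r$dclass %in% c("IgC2", "FnIII"))
      stop(sprintf("row %d (%s): unknown domain class '%s'", i, r$name, r$dclass))
    if (any(c(r$n_res, r$n_protected, r$linker_after) < 0) || r$d_fold < 0)
      stop(sprintf("row %d (%s): negative counts or folded span", i, r$name))
    if (r$n_protected > r$n_res)
      stop(sprintf("row %d (%s): n_protected exceeds n_res", i, r$name))
    if (r$dclass == "FnIII" && r$n_protected != 0)
      stop(sprintf("row %d (%s): FnIII domains carry no disulfide clamp (n_protected must be 0)",
                   i, r$name))
  }
  structure(list(domains = d, l_aa = l_aa), class = "protein_architecture")
}

#' The packaged CNTN4 architecture
#'
#' Convenience wrapper around [load_architecture()] for the packaged CNTN4
#' table (6 IgC2 + 4 FnIII domains).
#'
#' @inheritParams load_architecture
#' @return A `protein_architecture`.
#' @export
cntn4_architecture <- function(l_aa = 0.38) load_architecture(l_aa = l_aa)

#' @export
print.protein_architecture <- function(x, ...) {
  cat(sprintf("Protein architecture: %d domains (%d IgC2, %d FnIII), l_aa = %g nm/aa\n",
              nrow(x$domains), sum(x$domains$dclass == "IgC2"),
              sum(x$domains$dclass == "FnIII"), x$l_aa))
  print(x$domains, row.names = FALSE)
  invisible(x)
}

#' Predicted unfolding length of each domain
#'
#' Converts residue counts into the expected contour-length increment released
#' when a domain unfolds: the extensible residues times the per-residue
#' contour gain, minus the folded N-to-C span that the domain already
#' contributed before unfolding. For IgC2 domains only the residues outside
#' the disulfide bridge are extensible; the clamped span stays folded.
#' Predictions are floored at zero (a fully clamped domain releases nothing).
#'
#' @param arch A `protein_architecture`, or a single-row data.frame/list with
#'   the domain-table columns (`name`, `dclass`, `n_res`, `n_protected`,
#'   `linker_after`, `d_fold`).
#' @param l_aa Contour gain per residue (nm/aa); defaults to the
#'   architecture's own value.
#' @return Named numeric vector of predicted unfolding lengths (nm).
#' @export
predicted_unfolding_length <- function(arch, l_aa = NULL) {
  d <- if (inherits(arch, "protein_architecture")) {
    if (is.null(l_aa)) l_aa <- arch$l_aa
    arch$domains
  } else as.data.frame(arch, stringsAsFactors = FALSE)
  if (is.null(l_aa)) l_aa <- 0.38
  if (!is.numeric(l_aa) || length(l_aa) != 1L || l_aa <= 0 || l_aa >= 1)
    stop("'l_aa' must be in (0, 1) nm per residue")
  free <- ifelse(d$dclass == "FnIII", d$n_res, d$n_res - d$n_protected)
  out <- pmax(free * l_aa - d$d_fold, 0)
  names(out) <- d$name
  out
}

#' Unprotected contour length of each domain
#'
#' The hard physical ceiling on a domain's unfolding increment: the contour
#' length of the residues not sheltered by a disulfide bridge,
#' `(n_res - n_protected) * l_aa`.
#'
#' @inheritParams predicted_unfolding_length
#' @return Named numeric vector (nm).
#' @export
unprotected_contour <- function(arch, l_aa = NULL) {
  d <- if (inherits(arch, "protein_architecture")) {
    if (is.null(l_aa)) l_aa <- arch$l_aa
    arch$domains
  } else as.data.frame(arch, stringsAsFactors = FALSE)
  out <- (d$n_res - d$n_protected) * l_aa
  names(out) <- d$name
  out
}

#' Folded contour length of a (sub)construct
#'
#' Contour length presented by the still-folded chain: the folded N-to-C span
#' of each domain plus the stretched inter-domain linkers, plus a tether
#' offset accounting for attachment geometry at tip and surface.
#'
#' @param arch A `protein_architecture`.
#' @param tether_nm Additional non-protein tether length (nm).
#' @return Length in nm.
#' @export
folded_contour_length <- function(arch, tether_nm = 8) {
  stopifnot(inherits(arch, "protein_architecture"))
  d <- arch$domains
  sum(d$d_fold) + sum(utils::head(d$linker_after, -1)) * arch$l_aa + tether_nm
}
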