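# Buried-fragment enumeration and end-to-end distance collection.
#
# A fragment of sequence separation m spans residues i..i+m. It is "buried"
# when m < N^(2/3) (strict), with N the residue count of the chain: such
# fragments are short relative to the globule and hence likely to lie in its
# interior. All overlapping windows are pooled.

#' Enumerate buried fragments of one chain
#'
#' Returns all index pairs `(i, i + m)` (1-based) if and only if the chain
#' passes the buriedness test `m < N^(2/3)`; otherwise an empty matrix.
#'
#' @param chain an `fr_chain` (or an integer chain length N).
#' @param m sequence separation, >= 1.
#' @return integer matrix with columns `i`, `j` (zero rows when the chain is
#'   too short for burial at this separation).
#' @export
enumerate_buried_fragments <- function(chain, m) {
  stopifnot(m >= 1)
  n <- if (inherits(chain, "fr_chain")) chain$N else as.integer(chain)
  if (!(m < n^(2 / 3)) || m >= n)
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  i <- seq_len(n - m)
  cbind(i = i, j = i + m)
}

#' End-to-end distance between two residues
#'
#' CA: distance between the alpha carbons. HV: minimum distance over all
#' heavy-atom pairs. HH: minimum distance over all atom pairs, hydrogens
#' included.
#'
#' @param res_i,res_j residues as returned by [chain_residue].
#' @param level coarse-graining level.
#' @return distance in Angstrom.
#' @export
end_to_end_distance <- function(res_i, res_j, level = c("CA", "HV", "HH")) {
  level <- match_level(level[1L])
  a <- atom_selection(res_i, level)
  b <- atom_selection(res_j, level)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

new_fragment_set <- function(m, level, distances, terminal_types = NULL,
                             skipped = 0L) {
  structure(list(m = as.integer(m), level = level,
                 distances = as.numeric(distances),
                 terminal_types = terminal_types,
                 n = length(distances), skipped = as.integer(skipped)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> m = %d, level = %s, n = %d%s\n", x$m, x$level,
              x$n, if (x$skipped > 0)
                sprintf(" (%d skipped for missing atoms)", x$skipped) else ""))
  invisible(x)
}

# level-specific distances for all buried windows of one chain; NA where a
# needed atom is missing
chain_pair_distances <- function(ch, m, level, terminal_types = TRUE) {
  pairs <- enumerate_buried_fragments(ch, m)
  if (nrow(pairs) == 0L) return(NULL)
  if (level == "CA") {
    a <- ch$ca[pairs[, 1L], , drop = FALSE]
    b <- ch$ca[pairs[, 2L], , drop = FALSE]
    d <- sqrt(rowSums((a - b)^2))
  } else {
    d <- vapply(seq_len(nrow(pairs)), function(k) {
      ri <- chain_residue(ch, pairs[k, 1L])
      rj <- chain_residue(ch, pairs[k, 2L])
      tryCatch(end_to_end_distance(ri, rj, level),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  list(d = d,
       aa = if (terminal_types) cbind(ch$aa[pairs[, 1L]], ch$aa[pairs[, 2L]])
            else NULL)
}

#' Collect buried-fragment end-to-end distances by sequence separation
#'
#' Pools, for every separation m in `m_range`, the end-to-end distances of
#' all buried fragments across the ensemble at the requested coarse-graining
#' level, together with the residue types at the fragment ends. Fragments for
#' which a required atom is missing are skipped and counted, not imputed.
#'
#' @param chains a chain, structure, or list of either.
#' @param m_range integer vector `c(m_lo, m_hi)` (default 30-90) or an
#'   explicit vector of separations.
#' @param level coarse-graining level; HH on an ensemble without any
#'   hydrogen atoms is refused.
#' @param terminal_types record the residue types at the fragment ends
#'   (needed for the sequence-dependent pass; disable on very large
#'   ensembles to save memory).
#' @return Named list (by m) of `fragment_set` objects.
#' @export
collect_distances <- function(chains, m_range = c(30L, 90L),
                              level = c("CA", "HV", "HH"),
                              terminal_types = TRUE) {
  level <- match_level(level[1L])
  chains <- as_chain_list(chains)
  if (length(chains) == 0L) stop("empty chain ensemble")
  if (level == "HH" && !has_hydrogens(chains))
    stop("HH level requested but no hydrogen atoms anywhere in the ensemble; ",
         "use level = 'HV' explicitly if that is intended")
  ms <- if (length(m_range) == 2L) seq.int(m_range[1L], m_range[2L])
        else as.integer(m_range)
  out <- vector("list", length(ms))
  names(out) <- ms
  for (k in seq_along(ms)) {
    m <- ms[k]
    parts <- lapply(chains, chain_pair_distances, m = m, level = level,
                    terminal_types = terminal_types)
    parts <- parts[!vapply(parts, is.null, TRUE)]
    if (length(parts) == 0L) {
      out[[k]] <- new_fragment_set(m, level, numeric(0),
                                   if (terminal_types)
                                     matrix(character(0), 0L, 2L) else NULL)
      next
    }
    d <- unlist(lapply(parts, `[[`, "d"), use.names = FALSE)
    ok <- !is.na(d)
    aa <- if (terminal_types) {
      aam <- do.call(rbind, lapply(parts, `[[`, "aa"))
      aam[ok, , drop = FALSE]
    } else NULL
    out[[k]] <- new_fragment_set(m, level, d[ok], aa, skipped = sum(!ok))
  }
  if (all(vapply(out, function(f) f$n, 0L) == 0L))
    warning("no buried fragments collected for any separation in range")
  out
}

#' Restrict a fragment set to one unordered terminal residue-type pair
#'
#' @param fs a `fragment_set` carrying terminal types.
#' @param aa1,aa2 3-letter amino-acid codes; matching is unordered, so
#'   (ALA, GLY) keeps both ALA...GLY and GLY...ALA fragments.
#' @return a `fragment_set` with the matching subset.
#' @export
filter_by_terminal_types <- function(fs, aa1, aa2) {
  stopifnot(inherits(fs, "fragment_set"))
  if (is.null(fs$terminal_types))
    stop("fragment set carries no terminal residue types")
  aa1 <- toupper(aa1); aa2 <- toupper(aa2)
  for (a in c(aa1, aa2))
    if (!(a %in% AA3)) stop("unknown amino-acid code: ", a)
  tt <- fs$terminal_types
  keep <- (tt[, 1L] == aa1 & tt[, 2L] == aa2) |
          (tt[, 1L] == aa2 & tt[, 2L] == aa1)
  new_fragment_set(fs$m, fs$level, fs$distances[keep],
                   tt[keep, , drop = FALSE], skipped = fs$skipped)
}

#' Serialize fragment sets to a columnar TSV
#'
#' Columns: m, level, R, aa_i, aa_j. Reloading with [read_fragments] is
#' lossless up to the printed precision.
#'
#' @param fsets named list of `fragment_set` (as from [collect_distances]).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fragments <- function(fsets, path) {
  if (inherits(fsets, "fragment_set")) fsets <- list(fsets)
  tabs <- lapply(fsets, function(fs) {
    if (fs$n == 0L) return(NULL)
    tt <- fs$terminal_types
    if (is.null(tt)) tt <- matrix(NA_character_, fs$n, 2L)
    data.frame(m = fs$m, level = fs$level, R = fs$distances,
               aa_i = tt[, 1L], aa_j = tt[, 2L], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs[!vapply(tabs, is.null, TRUE)])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reload fragment sets written by [write_fragments]
#'
#' @param path TSV file.
#' @return named list of `fragment_set` objects, keyed by m.
#' @export
read_fragments <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$m), function(g)
    new_fragment_set(g$m[1L], g$level[1L], g$R,
                     cbind(g$aa_i, g$aa_j)))
  out[order(as.integer(names(out)))]
}
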