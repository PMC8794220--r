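# Structure ingestion: PDB/mmCIF -> per-chain residue coordinate sets at the
# three coarse-graining levels (CA / HV / HH).

#' Construct a chain object
#'
#' A chain is the unit of analysis: an ordered polypeptide with per-residue
#' coordinates. Coordinates are in Angstrom. `ca` must always be present
#' (one row per residue, `NA` rows allowed for residues without a resolved
#' alpha carbon); `atoms` is optional and only needed for the HV/HH
#' coarse-graining levels.
#'
#' @param ca numeric N x 3 matrix of alpha-carbon coordinates.
#' @param aa character vector of 3-letter residue codes (recycled if length 1).
#' @param atoms optional list of length N; element i is a list with fields
#'   `xyz` (k x 3 matrix), `name` (atom names) and `element` (element symbols,
#'   `"H"` marking hydrogens).
#' @param id chain identifier.
#' @param resno original residue numbering (defaults to 1..N).
#' @return An object of class `fr_chain` with fields `ca`, `aa`, `atoms`,
#'   `id`, `resno` and residue count `N`.
#' @export
new_chain <- function(ca, aa = "GLY", atoms = NULL, id = "A", resno = NULL) {
  ca <- as.matrix(ca)
  if (ncol(ca) != 3L) stop("`ca` must be an N x 3 coordinate matrix")
  n <- nrow(ca)
  if (n < 2L) stop("a chain needs at least 2 residues")
  aa <- rep_len(as.character(aa), n)
  if (!is.null(atoms) && length(atoms) != n)
    stop("`atoms` must have one entry per residue")
  if (is.null(resno)) resno <- seq_len(n)
  structure(list(ca = unname(ca), aa = aa, atoms = atoms, id = id,
                 resno = resno, N = n),
            class = "fr_chain")
}

#' @export
print.fr_chain <- function(x, ...) {
  cat(sprintf("<fr_chain %s> %d residues%s\n", x$id, x$N,
              if (is.null(x$atoms)) " (CA trace)" else " (full atoms)"))
  invisible(x)
}

#' @export
print.fr_structure <- function(x, ...) {
  cat(sprintf("<fr_structure %s> %d chain(s): %s\n", x$id, length(x$chains),
              paste(vapply(x$chains, function(ch)
                sprintf("%s(%d)", ch$id, ch$N), ""), collapse = ", ")))
  invisible(x)
}

#' Extract one residue from a chain
#'
#' Returns the residue's atom table in the form used by [atom_selection]:
#' a list with `xyz`, `name`, `element` and `aa`. CA-trace chains synthesise
#' a single-CA residue.
#'
#' @param chain an `fr_chain`.
#' @param i residue index (1-based).
#' @return list with fields `xyz`, `name`, `element`, `aa`.
#' @export
chain_residue <- function(chain, i) {
  stopifnot(inherits(chain, "fr_chain"), i >= 1L, i <= chain$N)
  if (is.null(chain$atoms)) {
    list(xyz = chain$ca[i, , drop = FALSE], name = "CA", element = "C",
         aa = chain$aa[i])
  } else {
    r <- chain$atoms[[i]]
    list(xyz = r$xyz, name = r$name, element = r$element, aa = chain$aa[i])
  }
}

#' Select residue coordinates for a coarse-graining level
#'
#' CA returns exactly the alpha-carbon coordinate; HV all heavy (non-hydrogen)
#' atoms; HH all atoms including hydrogens. The function does not silently
#' degrade: a missing CA at level CA, or no heavy atom at level HV, is an
#' error the caller decides how to handle.
#'
#' @param residue a residue as returned by [chain_residue] (fields `xyz`,
#'   `name`, `element`).
#' @param level one of `"CA"`, `"HV"`, `"HH"`.
#' @return matrix of selected coordinates (rows are atoms).
#' @export
atom_selection <- function(residue, level = c("CA", "HV", "HH")) {
  level <- match_level(level[1L])
  xyz <- residue$xyz
  if (level == "CA") {
    k <- which(residue$name == "CA")
    if (length(k) == 0L) stop("missing CA atom in residue")
    return(xyz[k[1L], , drop = FALSE])
  }
  if (level == "HV") {
    k <- which(!(residue$element %in% c("H", "D")))
    if (length(k) == 0L) stop("no heavy atom in residue")
    return(xyz[k, , drop = FALSE])
  }
  xyz
}

#' Does any residue of the structure/chain carry hydrogens?
#'
#' Used to refuse HH-level analysis on hydrogen-free inputs rather than
#' silently degrading to HV.
#'
#' @param x an `fr_chain`, `fr_structure`, or list of chains.
#' @return logical scalar.
#' @export
has_hydrogens <- function(x) {
  chains <- as_chain_list(x)
  for (ch in chains) {
    if (is.null(ch$atoms)) next
    for (r in ch$atoms) if (any(r$element %in% c("H", "D"))) return(TRUE)
  }
  FALSE
}

# Normalize the various "ensemble" arguments to a flat list of fr_chain.
as_chain_list <- function(x) {
  if (inherits(x, "fr_chain")) return(list(x))
  if (inherits(x, "fr_structure")) return(x$chains)
  if (is.list(x)) {
    out <- list()
    for (el in x) out <- c(out, as_chain_list(el))
    return(out)
  }
  stop("cannot interpret input as a chain ensemble")
}

#' Radius of gyration of a chain (CA level)
#'
#' Unweighted root-mean-square distance of the alpha-carbon coordinates from
#' their centroid, in Angstrom. Residues without a resolved CA are ignored.
#'
#' @param chain an `fr_chain`.
#' @return length in Angstrom.
#' @export
radius_of_gyration <- function(chain) {
  stopifnot(inherits(chain, "fr_chain"))
  ca <- chain$ca[stats::complete.cases(chain$ca), , drop = FALSE]
  if (nrow(ca) < 2L) stop("need at least 2 CA atoms for a radius of gyration")
  ctr <- colMeans(ca)
  sqrt(mean(rowSums(sweep(ca, 2L, ctr)^2)))
}

#' Read a protein structure from a PDB or mmCIF file
#'
#' Parses with bio3d and converts to the package's per-chain representation.
#' Conventions: only the first model of multi-model files is used; alternate
#' locations are resolved to the highest-occupancy copy (ties: first listed);
#' waters and ligands are dropped, but HETATM residues that carry a CA atom
#' (modified amino acids such as MSE) are retained; chains are split at gaps
#' in the residue numbering, since distances across unresolved regions are
#' meaningless.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param min_chain_len chains shorter than this (after break splitting) are
#'   dropped; default 2.
#' @return An `fr_structure`: list with `id`, `chains`, `source_path`.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           min_chain_len = 2L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     pdb = "pdb", ent = "pdb",
                     cif = "mmcif", mmcif = "mmcif",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  parsed <- tryCatch(
    if (format == "pdb") {
      suppressWarnings(suppressMessages(
        bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)))
    } else {
      suppressWarnings(suppressMessages(bio3d::read.cif(path)))
    },
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  # first model only (read.pdb multi = FALSE already keeps model 1; mmCIF
  # tables may still carry several models in some bio3d versions)
  if (!is.null(at$model) && length(unique(at$model)) > 1L)
    at <- at[at$model == at$model[1L], , drop = FALSE]
  at <- at[is.finite(at$x) & is.finite(at$y) & is.finite(at$z), , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms with finite coordinates in '", path, "'")
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  # drop waters/ligands: keep ATOM records and CA-carrying HETATM residues
  ca_res <- unique(rkey[at$elety == "CA" & !(at$elesy %in% c("H", "D"))])
  keep <- at$type == "ATOM" | rkey %in% ca_res
  at <- at[keep, , drop = FALSE]
  rkey <- rkey[keep]
  if (nrow(at) == 0L) stop("no protein residues in '", path, "'")
  # alt-loc resolution: within (residue, atom name) keep highest occupancy,
  # ties going to the first listed record
  occ <- ifelse(is.na(at$o), 1, at$o)
  akey <- paste(rkey, at$elety, sep = "|")
  ord <- order(akey, -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE][!duplicated(akey[ord]), , drop = FALSE]
  at <- at[order(match(paste(at$chain, at$resno, at$insert, sep = "|"),
                       unique(rkey))), , drop = FALSE]

  id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path), ignore.case = TRUE)
  chains <- list()
  for (cid in unique(at$chain)) {
    ca_t <- at[at$chain == cid, , drop = FALSE]
    res_split <- split(seq_len(nrow(ca_t)),
                       factor(paste(ca_t$resno, ca_t$insert, sep = "|"),
                              levels = unique(paste(ca_t$resno, ca_t$insert,
                                                    sep = "|"))))
    resno <- ca_t$resno[vapply(res_split, `[`, 0L, 1L)]
    # split at numbering gaps (chain breaks)
    brk <- cumsum(c(0L, diff(resno) != 1L))
    for (seg in unique(brk)) {
      ridx <- which(brk == seg)
      if (length(ridx) < min_chain_len) next
      n <- length(ridx)
      ca <- matrix(NA_real_, n, 3L)
      aa <- character(n)
      atoms <- vector("list", n)
      for (k in seq_len(n)) {
        rows <- ca_t[res_split[[ridx[k]]], , drop = FALSE]
        aa[k] <- rows$resid[1L]
        elem <- rows$elesy
        elem[is.na(elem) | elem == ""] <-
          substr(gsub("[0-9]", "", rows$elety[is.na(elem) | elem == ""]), 1, 1)
        atoms[[k]] <- list(xyz = cbind(rows$x, rows$y, rows$z),
                           name = rows$elety, element = elem)
        kca <- which(rows$elety == "CA" & !(elem %in% c("H", "D")))
        if (length(kca)) ca[k, ] <- c(rows$x[kca[1]], rows$y[kca[1]],
                                      rows$z[kca[1]])
      }
      cid_lab <- if (length(unique(brk)) > 1L)
        paste0(cid, ".", seg + 1L) else cid
      chains[[length(chains) + 1L]] <-
        new_chain(ca, aa, atoms, id = cid_lab, resno = resno[ridx])
    }
  }
  if (length(chains) == 0L)
    stop("no chain with >= ", min_chain_len, " residues in '", path, "'")
  structure(list(id = id, chains = chains, source_path = path),
            class = "fr_structure")
}
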