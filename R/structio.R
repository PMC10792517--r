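# Structure and table I/O, residue correspondence, evaluation-unit
# restriction, confidence extraction and MSA depth.
#
# PDB/mmCIF parsing is delegated to bio3d; this layer enforces the
# assessment's conventions (heavy atoms only, one conformer per atom,
# standard residues) and carries crystal cell metadata, which bio3d's
# containers do not.

res_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")

new_structure <- function(atoms, id = "struct", cell = NULL, space_group = NULL,
                          role = c("target", "prediction")) {
  role <- match.arg(role)
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, cell = cell,
                 space_group = space_group, role = role),
            class = "mc_structure")
}

#' @export
print.mc_structure <- function(x, ...) {
  cat(sprintf("<mc_structure %s: %d atoms, %d residues, role=%s%s>\n",
              x$id, nrow(x$atoms), n_residues(x), x$role,
              if (!is.null(x$cell)) sprintf(", cell=%s %s",
                paste(signif(x$cell, 4), collapse = " "),
                x$space_group %||% "") else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

n_residues <- function(x) length(unique(res_key(x$atoms)))

# Residue table in file order: key, chain, resno, insert, type, CA atom row.
residue_table <- function(x) {
  k <- res_key(x$atoms)
  first <- !duplicated(k)
  tab <- data.frame(key = k[first], chain = x$atoms$chain[first],
                    resno = x$atoms$resno[first], insert = x$atoms$insert[first],
                    type = x$atoms$resid[first], stringsAsFactors = FALSE)
  ca <- rep(NA_integer_, nrow(tab))
  is_ca <- which(x$atoms$elety == "CA")
  ca[match(k[is_ca], tab$key)] <- is_ca
  tab$ca <- ca
  tab
}

atom_xyz <- function(x, idx = NULL) {
  a <- x$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

# Return rows of x$atoms belonging to the given residue keys, in order.
atoms_of <- function(x, keys) {
  which(res_key(x$atoms) %in% keys)
}

parse_cryst1 <- function(lines) {
  ln <- grep("^CRYST1", lines, value = TRUE)
  if (!length(ln)) return(NULL)
  ln <- ln[1]
  cell <- suppressWarnings(as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24),
                                        substr(ln, 25, 33), substr(ln, 34, 40),
                                        substr(ln, 41, 47), substr(ln, 48, 54))))
  sg <- trimws(substr(ln, 56, 66))
  if (any(is.na(cell))) return(NULL)
  list(cell = cell, space_group = if (nzchar(sg)) sg else "P 1")
}

parse_cif_cell <- function(lines) {
  getval <- function(tag) {
    ln <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (!length(ln)) return(NA)
    trimws(sub(paste0("^", tag, "\\s+"), "", ln[1]))
  }
  vals <- suppressWarnings(as.numeric(c(
    getval("_cell.length_a"), getval("_cell.length_b"), getval("_cell.length_c"),
    getval("_cell.angle_alpha"), getval("_cell.angle_beta"), getval("_cell.angle_gamma"))))
  if (any(is.na(vals))) return(NULL)
  sg <- getval("_symmetry.space_group_name_H-M")
  if (is.na(sg)) sg <- "P 1"
  sg <- gsub("^['\"]|['\"]$", "", sg)
  list(cell = vals, space_group = sg)
}

#' Read a structure from PDB or mmCIF
#'
#' Parses a structure for assessment: hydrogens are dropped, alternate
#' locations resolved to the highest-occupancy conformer (ties favour
#' altloc "A"), HETATM/non-standard residues discarded, and the CRYST1 /
#' `_cell` crystal metadata captured when present.
#'
#' @param path File path.
#' @param format `"pdb"` or `"mmcif"`; default guessed from the extension.
#' @param id Identifier stored on the structure; defaults to the file stem.
#' @param role `"target"` or `"prediction"`. Predictions carry pLDDT in the
#'   B-factor column; targets may carry a crystal cell.
#' @return An `mc_structure`.
#' @export
read_structure <- function(path, format = NULL, id = NULL,
                           role = c("target", "prediction")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  format <- match.arg(format, c("pdb", "mmcif"))
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("unparseable ", format, " file: ", path,
                             " (", conditionMessage(e), ")"))
  atoms <- pdb$atom
  lines <- readLines(path, warn = FALSE)
  meta <- if (format == "pdb") parse_cryst1(lines) else parse_cif_cell(lines)
  atoms <- atoms[atoms$type == "ATOM" & atoms$resid %in% AA3, , drop = FALSE]
  if (!nrow(atoms)) stop("empty structure (no standard protein ATOM records): ", path)
  # element fallback from the atom name
  if (is.null(atoms$elesy) || all(is.na(atoms$elesy))) {
    atoms$elesy <- substr(gsub("[0-9]", "", atoms$elety), 1, 1)
  }
  atoms <- atoms[!(toupper(atoms$elesy) %in% c("H", "D")), , drop = FALSE]
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  # altloc resolution: per (residue, atom name) keep highest occupancy,
  # ties by altloc letter (so 'A' wins).
  akey <- paste(res_key(atoms), atoms$elety)
  if (anyDuplicated(akey)) {
    ord <- order(akey, -atoms$o, atoms$alt)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(res_key(atoms), atoms$elety)), , drop = FALSE]
    atoms <- atoms[order(match(res_key(atoms), unique(res_key(pdb$atom)))), , drop = FALSE]
  }
  keep <- c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
            "insert", "x", "y", "z", "o", "b", "elesy")
  atoms <- atoms[, intersect(keep, names(atoms)), drop = FALSE]
  if (is.null(id)) id <- sub("\\.(pdb|cif|ent)$", "", basename(path), ignore.case = TRUE)
  new_structure(atoms, id = id, cell = meta$cell, space_group = meta$space_group,
                role = role)
}

#' Write a structure to PDB
#'
#' Writes atoms via bio3d and prepends a CRYST1 record when the structure
#' carries a crystal cell.
#'
#' @param x An `mc_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  a <- x$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain, insert = a$insert,
                   o = a$o, b = a$b, elesy = a$elesy)
  if (!is.null(x$cell)) {
    ln <- readLines(path, warn = FALSE)
    cry <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                   x$cell[1], x$cell[2], x$cell[3], x$cell[4], x$cell[5],
                   x$cell[6], x$space_group %||% "P 1", 1L)
    writeLines(c(cry, ln), path)
  }
  invisible(path)
}

# Needleman-Wunsch global alignment on one-letter sequences
# (match +1 / mismatch -1 / gap -2); returns index pairs (i in a, j in b).
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  n <- length(a); m <- length(b)
  sc <- matrix(0, n + 1, m + 1)
  sc[, 1] <- gap * (0:n)
  sc[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m)) {
      sc[i + 1, j + 1] <- max(sc[i, j] + sub[j], sc[i, j + 1] + gap, sc[i + 1, j] + gap)
    }
  }
  i <- n; j <- m
  pi <- integer(0); pj <- integer(0)
  while (i > 0 && j > 0) {
    s <- if (a[i] == b[j]) match else mismatch
    if (sc[i + 1, j + 1] == sc[i, j] + s) {
      pi <- c(i, pi); pj <- c(j, pj); i <- i - 1; j <- j - 1
    } else if (sc[i + 1, j + 1] == sc[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  cbind(pi, pj)
}

#' Match model residues to target residues
#'
#' Primary matching is by author numbering (chain, residue number, insertion
#' code). When fewer than half of the target residues match this way, the
#' matching falls back to a per-chain global sequence alignment of the
#' one-letter sequences. Pairs whose residue types differ are retained (their
#' backbone still scores) but flagged, and side-chain metrics skip them.
#'
#' @param target,model `mc_structure` objects.
#' @return An `mc_map`: pair table, frame size (number of target residues the
#'   metrics are normalised against) and coverage.
#' @export
map_residues <- function(target, model) {
  rt <- residue_table(target)
  rm_ <- residue_table(model)
  if (!nrow(rt) || !nrow(rm_)) stop("empty structure")
  m <- match(rt$key, rm_$key)
  if (mean(!is.na(m)) < 0.5) {
    # alignment fallback, per target chain against each model chain (best)
    m <- rep(NA_integer_, nrow(rt))
    for (ch in unique(rt$chain)) {
      ti <- which(rt$chain == ch)
      best <- NULL; best_score <- -Inf
      for (mch in unique(rm_$chain)) {
        mi <- which(rm_$chain == mch)
        al <- nw_align(aa_three_to_one(rt$type[ti]), aa_three_to_one(rm_$type[mi]))
        if (!nrow(al)) next
        score <- sum(aa_three_to_one(rt$type[ti])[al[, 1]] ==
                     aa_three_to_one(rm_$type[mi])[al[, 2]])
        if (score > best_score) { best_score <- score; best <- cbind(ti[al[, 1]], mi[al[, 2]]) }
      }
      if (!is.null(best)) m[best[, 1]] <- best[, 2]
    }
  }
  ok <- !is.na(m)
  if (!any(ok)) stop("no residues could be matched between target and model")
  pairs <- data.frame(t_key = rt$key[ok], m_key = rm_$key[m[ok]],
                      t_type = rt$type[ok], m_type = rm_$type[m[ok]],
                      stringsAsFactors = FALSE)
  pairs$same_type <- pairs$t_type == pairs$m_type
  structure(list(target = target, model = model, pairs = pairs,
                 frame_keys = rt$key, coverage = nrow(pairs) / nrow(rt)),
            class = "mc_map")
}

#' @export
print.mc_map <- function(x, ...) {
  cat(sprintf("<mc_map %s ~ %s: %d/%d residues matched (coverage %.2f)>\n",
              x$target$id, x$model$id, nrow(x$pairs), length(x$frame_keys),
              x$coverage))
  invisible(x)
}

# Parse an EU selection string like "A:1-120+A:180-210".
parse_selection <- function(s) {
  parts <- strsplit(s, "+", fixed = TRUE)[[1]]
  do.call(rbind, lapply(parts, function(p) {
    mm <- regmatches(p, regexec("^([^:]+):(-?[0-9]+)-(-?[0-9]+)$", p))[[1]]
    if (length(mm) != 4) stop("bad selection syntax: ", p)
    data.frame(chain = mm[2], start = as.integer(mm[3]), end = as.integer(mm[4]),
               stringsAsFactors = FALSE)
  }))
}

#' Read an evaluation-unit definition table
#'
#' TSV with header `target_id eu_id selection difficulty taxonomy`;
#' selection syntax `A:1-120+A:180-210`.
#'
#' @param path TSV path.
#' @return Data frame with a parsed `ranges` list-column.
#' @export
read_eu_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("target_id", "eu_id", "selection", "difficulty", "taxonomy")
  if (!all(need %in% names(tab))) stop("EU table must have columns: ",
                                       paste(need, collapse = " "))
  diffs <- c("TBM-easy", "TBM-hard", "FM/TBM", "FM")
  taxa <- c("Bacteria", "Archaea", "Virus", "Eukaryote", "Synthetic")
  if (!all(tab$difficulty %in% diffs)) stop("unknown difficulty class")
  if (!all(tab$taxonomy %in% taxa)) stop("unknown taxonomy")
  tab$ranges <- lapply(tab$selection, parse_selection)
  tab
}

eu_unit <- function(eu_id, ranges, target_id = "T0000",
                    difficulty = "FM", taxonomy = "Synthetic") {
  list(target_id = target_id, eu_id = eu_id, ranges = ranges,
       difficulty = difficulty, taxonomy = taxonomy)
}

#' Restrict a correspondence map to an evaluation unit
#'
#' Keeps only pairs whose target residue lies inside the EU's residue
#' ranges; coverage is recomputed against the EU length, which also becomes
#' the frame for coverage-penalised metrics.
#'
#' @param map An `mc_map`.
#' @param eu A row of [read_eu_table()] output, or a list with a `ranges`
#'   data frame (`chain`, `start`, `end`).
#' @return A restricted `mc_map`.
#' @export
restrict_to_eu <- function(map, eu) {
  ranges <- if (is.data.frame(eu$ranges)) eu$ranges else eu$ranges[[1]]
  rt <- residue_table(map$target)
  insel <- rep(FALSE, nrow(rt))
  for (i in seq_len(nrow(ranges))) {
    insel <- insel | (rt$chain == ranges$chain[i] &
                      rt$resno >= ranges$start[i] & rt$resno <= ranges$end[i])
  }
  if (!any(insel)) stop("EU selection matches no target residues")
  frame_keys <- rt$key[insel]
  pairs <- map$pairs[map$pairs$t_key %in% frame_keys, , drop = FALSE]
  if (!nrow(pairs)) stop("no matched residues inside the EU")
  structure(list(target = map$target, model = map$model, pairs = pairs,
                 frame_keys = frame_keys,
                 coverage = nrow(pairs) / length(frame_keys)),
            class = "mc_map")
}

#' Extract per-atom or per-residue confidence (pLDDT)
#'
#' Reads the B-factor column of a prediction. Suspicious scales — values
#' outside 0-100, or all values at most 1 (a 0-1 scale in a 0-100 field) —
#' are passed through unmodified with a warning; no rescaling is ever
#' attempted.
#'
#' @param model A prediction `mc_structure`.
#' @param granularity `"residue"` (mean over the residue's atoms) or
#'   `"atom"`.
#' @return Named numeric vector (residue keys or atom indices).
#' @export
extract_confidence <- function(model, granularity = c("residue", "atom")) {
  granularity <- match.arg(granularity)
  if (model$role != "prediction") stop("confidence is read from predictions")
  b <- model$atoms$b
  if (any(b < 0 | b > 100, na.rm = TRUE) || all(b <= 1, na.rm = TRUE)) {
    warning("confidence values look off-scale; passed through unmodified")
  }
  if (granularity == "atom") return(b)
  k <- res_key(model$atoms)
  v <- tapply(b, k, mean)
  as.numeric(v[unique(k)]) -> out
  names(out) <- unique(k)
  out
}

# Read an aligned FASTA or A3M file into an uppercase character vector
# (one string per sequence); A3M lowercase insertion columns are removed.
read_msa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  seqs <- vapply(seqs, function(s) gsub("[a-z.]", "", s), "")
  unname(seqs)
}

#' MSA depth as Neff divided by query length
#'
#' Neff is the effective number of sequences after identity clustering:
#' each sequence contributes 1 / (number of alignment members, itself
#' included, with pairwise identity at or above the threshold). The sum is
#' divided by the ungapped length of the first (query) sequence. Pairwise
#' identity is computed over columns where both sequences have residues.
#'
#' @param msa Character vector of equal-length aligned sequences, or a path
#'   to a FASTA/A3M file (A3M insertions dropped).
#' @param identity_threshold Clustering threshold, default 0.8.
#' @return Neff / length, a positive scalar.
#' @export
neff_per_length <- function(msa, identity_threshold = mc_defaults()$neff_identity_threshold) {
  if (length(msa) == 1 && file.exists(msa)) msa <- read_msa(msa)
  if (!length(msa)) stop("empty MSA")
  if (length(unique(nchar(msa))) != 1) stop("aligned sequences must have equal length")
  chars <- strsplit(toupper(msa), "")
  mat <- do.call(rbind, chars)
  n <- nrow(mat)
  qlen <- sum(mat[1, ] != "-")
  if (qlen == 0) stop("query sequence is all gaps")
  counts <- integer(n)
  for (i in seq_len(n)) {
    resi <- mat[i, ] != "-"
    for (j in seq_len(n)) {
      both <- resi & (mat[j, ] != "-")
      id <- if (any(both)) mean(mat[i, both] == mat[j, both]) else 0
      if (id >= identity_threshold) counts[i] <- counts[i] + 1L
    }
  }
  sum(1 / counts) / qlen
}
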