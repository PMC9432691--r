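# Sequence and structure utilities for phytase classification: FASTA I/O,
# degenerate motif scanning for histidine-acid-phytase / MINPP signatures,
# theoretical protein mass, and the ligand-pocket distance rule.

.AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# average (not monoisotopic) residue masses in Da, plus one water per chain
.AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.0153

#' Read protein sequences from a FASTA file
#'
#' Sequences may be wrapped or single-line; they are uppercased. Only the 20
#' standard one-letter codes are accepted, plus `X` (permitted but flagged
#' with a warning). Any other character is a parse error naming the line and
#' position.
#'
#' @param path FASTA file.
#' @return list of `protein_record` objects (list with `id`, `desc`,
#'   `sequence`).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !any(nzchar(trimws(lines)))) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  records <- list()
  id <- NULL; desc <- ""; seq_parts <- character()
  flush <- function() {
    if (is.null(id)) return()
    s <- toupper(paste(seq_parts, collapse = ""))
    if (!nzchar(s)) stop("record ", sQuote(id), " has an empty sequence", call. = FALSE)
    records[[length(records) + 1L]] <<- structure(
      list(id = id, desc = desc, sequence = s), class = "protein_record")
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      flush()
      header <- sub("^>", "", ln)
      id <- sub("\\s.*$", "", header)
      desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
      seq_parts <- character()
    } else {
      if (is.null(id)) {
        stop("FASTA parse error at line ", i, ": sequence before any header",
             call. = FALSE)
      }
      bad <- regexpr(paste0("[^", paste(.AA_CODES, collapse = ""), "Xx",
                            tolower(paste(.AA_CODES, collapse = "")), "]"), ln)
      if (bad > 0) {
        stop(sprintf("FASTA parse error at line %d, position %d: illegal residue %s",
                     i, bad, sQuote(substr(ln, bad, bad))), call. = FALSE)
      }
      seq_parts <- c(seq_parts, ln)
    }
  }
  flush()
  if (length(records) == 0) stop("no FASTA records in ", path, call. = FALSE)
  for (r in records) {
    if (grepl("X", r$sequence, fixed = TRUE)) {
      warning("record ", sQuote(r$id), " contains X (unknown residue)")
    }
  }
  records
}

#' Write protein records to a FASTA file
#' @param records list of `protein_record` (or named character vector).
#' @param path output file.
#' @param width line-wrap width (default 60).
#' @return invisibly, the path.
#' @export
write_fasta <- function(records, path, width = 60) {
  if (is.character(records)) {
    records <- Map(function(id, s) list(id = id, desc = "", sequence = s),
                   names(records), unname(records))
  }
  con <- file(path, "w"); on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$desc %||% "")) paste(r$id, r$desc) else r$id
    writeLines(paste0(">", header), con)
    s <- r$sequence
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' @export
print.protein_record <- function(x, ...) {
  cat(">", x$id, if (nzchar(x$desc)) x$desc, "\n")
  cat(" ", nchar(x$sequence), "aa;",
      substr(x$sequence, 1, 40),
      if (nchar(x$sequence) > 40) "..." else "", "\n")
  invisible(x)
}

#' Motifs diagnostic of histidine acid phytases and MINPPs
#'
#' The default motif set for [scan_motifs()]: the catalytic heptapeptide in
#' a generalised form `RHGxRx[PL]` (covering the canonical HAPhy `RHGxRxP`
#' and the MINPP variant `RHGSRGL`), the proton-donor dipeptide `HD` and the
#' MINPP tripeptide variant `HAE`, the MINPP-specific `PMAAN` and `LYNE`
#' beta-sheet motifs, and the U-loop flanking tetrapeptide `DAA[AM]`.
#'
#' @return named character vector of motif expressions (grammar: literal
#'   residues, `x` = any residue, `[..]` = single-position alternatives).
#' @export
phytase_motifs <- function() {
  c(heptapeptide = "RHGxRx[PL]",
    HD = "HD",
    HAE = "HAE",
    PMAAN = "PMAAN",
    LYNE = "LYNE",
    uloop_tetrapeptide = "DAA[AM]")
}

# parse a motif expression into a list of per-position character sets
.parse_motif <- function(expr) {
  chars <- strsplit(expr, "")[[1]]
  sets <- list(); i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      sets[[length(sets) + 1L]] <- .AA_CODES
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L; alt <- character()
      while (j <= length(chars) && chars[j] != "]") {
        if (!chars[j] %in% .AA_CODES) {
          stop("malformed motif ", sQuote(expr), ": bad residue in alternatives",
               call. = FALSE)
        }
        alt <- c(alt, chars[j]); j <- j + 1L
      }
      if (j > length(chars) || length(alt) == 0) {
        stop("malformed motif ", sQuote(expr), ": unterminated or empty [..]",
             call. = FALSE)
      }
      sets[[length(sets) + 1L]] <- alt
      i <- j + 1L
    } else if (ch %in% .AA_CODES) {
      sets[[length(sets) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("malformed motif ", sQuote(expr), ": illegal character ", sQuote(ch),
           call. = FALSE)
    }
  }
  if (length(sets) == 0) stop("empty motif expression", call. = FALSE)
  sets
}

#' Scan a protein sequence for degenerate motifs
#'
#' Finds every match start (overlaps between different starts allowed) of
#' each motif. Motif grammar: literal one-letter residues, `x` for any
#' residue, `[..]` for single-position alternatives — deliberately not full
#' regular expressions, so hits stay auditable.
#'
#' @param record a `protein_record` (or a bare sequence string).
#' @param motifs named character vector of motif expressions; default
#'   [phytase_motifs()].
#' @return data.frame `motif_id`, `start` (1-based), `match` (matched text),
#'   ordered by start then motif id.
#' @export
scan_motifs <- function(record, motifs = phytase_motifs()) {
  seq <- if (is.character(record)) toupper(record) else record$sequence
  if (is.null(names(motifs))) names(motifs) <- motifs
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  hits <- list()
  for (m in seq_along(motifs)) {
    sets <- .parse_motif(motifs[[m]])
    L <- length(sets)
    if (L > n) next
    for (s in seq_len(n - L + 1L)) {
      ok <- TRUE
      for (p in seq_len(L)) {
        if (!chars[s + p - 1L] %in% sets[[p]]) { ok <- FALSE; break }
      }
      if (ok) {
        hits[[length(hits) + 1L]] <- data.frame(
          motif_id = names(motifs)[m], start = s,
          match = substr(seq, s, s + L - 1L), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(motif_id = character(), start = integer(),
                      match = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, hits)
  res <- res[order(res$start, res$motif_id), ]
  rownames(res) <- NULL
  res
}

#' Classify a phytase sequence from its motif hits
#'
#' `MINPP_like` requires the catalytic heptapeptide plus at least one
#' MINPP-specific motif (`PMAAN`, `LYNE` or the U-loop tetrapeptide
#' `DAA[AM]`); `HAPhy_like` requires the heptapeptide and the `HD`
#' proton-donor motif without any MINPP motif; anything else is
#' `unclassified`.
#'
#' @param hits data.frame from [scan_motifs()] (default motif set).
#' @return list with `class` (`"MINPP_like"`, `"HAPhy_like"` or
#'   `"unclassified"`) and `rationale`.
#' @export
classify_phytase <- function(hits) {
  ids <- unique(hits$motif_id)
  has <- function(x) x %in% ids
  minpp_motifs <- intersect(c("PMAAN", "LYNE", "uloop_tetrapeptide"), ids)
  if (has("heptapeptide") && length(minpp_motifs) > 0) {
    list(class = "MINPP_like",
         rationale = paste0("catalytic heptapeptide present plus MINPP-specific motif(s): ",
                            paste(minpp_motifs, collapse = ", ")))
  } else if (has("heptapeptide") && has("HD")) {
    list(class = "HAPhy_like",
         rationale = "catalytic heptapeptide and HD proton donor, no MINPP-specific motifs")
  } else {
    list(class = "unclassified",
         rationale = paste0("insufficient motif evidence (found: ",
                            if (length(ids)) paste(ids, collapse = ", ") else "none",
                            ")"))
  }
}

#' Theoretical average protein mass
#'
#' Sum of average residue masses plus one water, in kDa. `X` or any
#' non-standard residue is an error listing the offending positions.
#'
#' @param record a `protein_record` or bare sequence string.
#' @param digits decimals for rounding the kDa value (default 2, the
#'   convention of common sequence tools); use `NULL` for no rounding.
#' @return mass in kDa.
#' @examples
#' theoretical_mass("G")   # 0.07507
#' theoretical_mass("GG")  # 0.13212
#' @export
theoretical_mass <- function(record, digits = 2) {
  seq <- if (is.character(record)) toupper(record) else record$sequence
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% .AA_CODES)
  if (length(bad)) {
    stop("non-standard residue(s) ", paste(unique(chars[bad]), collapse = ", "),
         " at position(s) ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  kda <- (sum(.AA_AVG_MASS[chars]) + .WATER_MASS) / 1000
  if (is.null(digits)) kda else round(kda, digits)
}

# --- structure: ligand-pocket distance rule ---------------------------------

.read_pdb_atoms <- function(pdb) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  a <- pdb$atom
  data.frame(type = a$type, eleno = a$eleno, elety = a$elety,
             resid = a$resid, chain = a$chain, resno = a$resno,
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}

#' Residues forming a ligand phosphate pocket
#'
#' For each phosphorus (or sulfur, for hexakissulfate substrate analogues)
#' atom of a bound ligand, lists every protein residue having ANY atom
#' within the distance cutoff of that atom, with the minimum residue-to-atom
#' distance. This is the classic specificity-pocket rule: the residues lying
#' within 5 Angstrom of the phosphorus of each substrate phosphate group.
#'
#' @param pdb path to a PDB file or a `bio3d` pdb object.
#' @param ligand_resid residue name(s) of the ligand (e.g. `"IHP"`); default:
#'   all HETATM residues.
#' @param atom_names names of the ligand atoms to measure from (default:
#'   atoms whose element is phosphorus, i.e. name starting with `"P"`; pass
#'   e.g. `"^S"` for sulfate analogues). Interpreted as a regular expression.
#' @param cutoff distance cutoff in Angstrom (default 5.0, closed interval).
#' @return data.frame `ligand_atom`, `chain`, `resno`, `resid`,
#'   `min_distance`, ordered by ligand atom, then chain, then residue number.
#' @export
pocket_residues <- function(pdb, ligand_resid = NULL, atom_names = "^P",
                            cutoff = 5.0) {
  atoms <- .read_pdb_atoms(pdb)
  is_lig <- atoms$type == "HETATM"
  if (!is.null(ligand_resid)) is_lig <- is_lig & atoms$resid %in% ligand_resid
  lig <- atoms[is_lig & grepl(atom_names, atoms$elety), ]
  if (nrow(lig) == 0) stop("no ligand atoms matched", call. = FALSE)
  prot <- atoms[atoms$type == "ATOM", ]
  if (nrow(prot) == 0) stop("no protein atoms in structure", call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(lig))) {
    d <- sqrt((prot$x - lig$x[i])^2 + (prot$y - lig$y[i])^2 + (prot$z - lig$z[i])^2)
    prot$d <- d
    near <- prot[d <= cutoff, ]
    if (nrow(near) == 0) next
    agg <- stats::aggregate(d ~ chain + resno + resid, data = near, FUN = min)
    agg <- agg[order(agg$chain, agg$resno), ]
    out[[length(out) + 1L]] <- data.frame(
      ligand_atom = paste0(lig$elety[i], "/", lig$eleno[i]),
      chain = agg$chain, resno = agg$resno, resid = agg$resid,
      min_distance = agg$d, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(ligand_atom = character(), chain = character(),
                      resno = integer(), resid = character(),
                      min_distance = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
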