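#' Parse a phospho-annotated peptide notation
#'
#' Reads the plain-text dialect used for synthetic phosphopeptides: an
#' uppercase one-letter sequence in which each phosphorylated serine or
#' threonine is written as the token `pS` or `pT`, with an optional
#' N-terminal prefix `Ac-` (acetyl) or `FAM-Ahx-` (5,6-carboxyfluorescein
#' via an aminohexanoic linker) and an optional C-terminal suffix `-NH2`
#' (amide) or `-OH` (free acid). Termini default to free/free-acid when no
#' prefix/suffix is given.
#'
#' @param notation Peptide string, e.g. `"Ac-DCRRTIpSAPVVRPK-NH2"`.
#' @param id Optional identifier carried through to reports.
#' @param protein_offset Integer mapping local residue 1 to full-protein
#'   numbering (e.g. 361 for a peptide spanning residues 361-374).
#' @return An object of class `"peptide_record"`: a list with `id`,
#'   `residues` (character vector of one-letter codes), `phospho_positions`
#'   (1-based local indices), `protein_offset`, `n_terminus` (one of
#'   `"acetyl"`, `"FAM-Ahx"`, `"free"`) and `c_terminus` (`"amide"` or
#'   `"free-acid"`).
#' @examples
#' parse_phosphopeptide("Ac-DCRRTIpSAPVVRPK-NH2", protein_offset = 361)
#' @export
parse_phosphopeptide <- function(notation, id = NULL, protein_offset = 1L) {
  stopifnot(is.character(notation), length(notation) == 1, nzchar(notation))
  protein_offset <- as.integer(protein_offset)

  body <- notation
  n_terminus <- "free"
  c_terminus <- "free-acid"
  if (startsWith(body, "FAM-Ahx-")) {
    n_terminus <- "FAM-Ahx"
    body <- substring(body, nchar("FAM-Ahx-") + 1L)
  } else if (startsWith(body, "Ac-")) {
    n_terminus <- "acetyl"
    body <- substring(body, nchar("Ac-") + 1L)
  }
  if (endsWith(body, "-NH2")) {
    c_terminus <- "amide"
    body <- substring(body, 1L, nchar(body) - 4L)
  } else if (endsWith(body, "-OH")) {
    c_terminus <- "free-acid"
    body <- substring(body, 1L, nchar(body) - 3L)
  }
  if (!nzchar(body)) stop("empty peptide sequence in notation")

  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  residues <- character(0)
  phospho <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "p") {
      nxt <- if (i < length(chars)) chars[i + 1L] else ""
      if (!nxt %in% c("S", "T")) {
        stop(sprintf(
          "malformed notation: phospho tag 'p' must precede S or T, found 'p%s'",
          nxt))
      }
      residues <- c(residues, nxt)
      phospho <- c(phospho, length(residues))
      i <- i + 2L
    } else {
      if (!ch %in% aa) {
        stop(sprintf("unknown residue letter '%s' (canonical alphabet only)",
                     ch))
      }
      residues <- c(residues, ch)
      i <- i + 1L
    }
  }
  structure(
    list(id = id, residues = residues, phospho_positions = phospho,
         protein_offset = protein_offset,
         n_terminus = n_terminus, c_terminus = c_terminus),
    class = "peptide_record"
  )
}

#' @export
print.peptide_record <- function(x, ...) {
  seq <- x$residues
  for (p in rev(x$phospho_positions)) seq[p] <- paste0("p", seq[p])
  cat(sprintf("<peptide_record%s> %s\n",
              if (!is.null(x$id)) paste0(" ", x$id) else "",
              paste(seq, collapse = "")))
  cat(sprintf("  %d residues (protein %d-%d), N-term %s, C-term %s\n",
              length(x$residues), x$protein_offset,
              x$protein_offset + length(x$residues) - 1L,
              x$n_terminus, x$c_terminus))
  if (length(x$phospho_positions)) {
    cat("  phosphosites at protein position(s):",
        paste(x$protein_offset + x$phospho_positions - 1L, collapse = ", "),
        "\n")
  }
  invisible(x)
}

# anchors individually satisfied around one phosphosite, as a named integer
# vector of signed offsets (e.g. Arg = -3, Pro = +2)
.motif_anchors <- function(residues, i) {
  n <- length(residues)
  at <- function(off) if (i + off >= 1 && i + off <= n) residues[i + off] else NA
  anchors <- integer(0)
  if (identical(at(-3L), "R")) anchors <- c(anchors, Arg = -3L)
  if (identical(at(-5L), "R")) anchors <- c(anchors, Arg = -5L)
  if (isTRUE(at(-3L) %in% c("Y", "F"))) anchors <- c(anchors, Aromatic = -3L)
  if (identical(at(2L), "P")) anchors <- c(anchors, Pro = 2L)
  anchors
}

#' Classify phosphosites against the canonical 14-3-3 recognition modes
#'
#' 14-3-3 client phosphosites fall into three canonical recognition
#' sequences: mode I `R-X-X-pS/pT-X-P`, mode II `R-X-(Y/F)-X-pS/pT-X-P`,
#' and mode III `X-X-pS/pT-X-COOH` (a C-terminal sequence in which the
#' phosphosite is the penultimate residue of the protein). Modes I and II
#' require the full anchor window to lie within the peptide; mode III
#' requires a free-acid C terminus, so synthetic amidated peptides can
#' never match it. When several definitions match one site, the single
#' reported label follows the priority II > I > III (mode II is the more
#' specific superset of the mode I anchors).
#'
#' @param p A [parse_phosphopeptide()] record.
#' @return A data frame with one row per phosphosite: `phospho_position`
#'   (local 1-based), `protein_position`, `residue` (`"S"`/`"T"`), `mode`
#'   (`"I"`, `"II"`, `"III"` or `"none"`), and a list-column `anchors`
#'   of named signed offsets for the individually satisfied anchor
#'   residues (reported even when no full mode matches). Zero rows when
#'   the peptide carries no phosphosites.
#' @examples
#' rec <- parse_phosphopeptide("Ac-DCRRTIpSAPVVRPK-NH2", protein_offset = 361)
#' scan_modes(rec)
#' @export
scan_modes <- function(p) {
  stopifnot(inherits(p, "peptide_record"))
  res <- p$residues
  n <- length(res)
  rows <- lapply(p$phospho_positions, function(i) {
    anchors <- .motif_anchors(res, i)
    has <- function(name, off) {
      any(names(anchors) == name & anchors == off)
    }
    mode <- "none"
    if (i - 5L >= 1L && i + 2L <= n &&
        has("Arg", -5L) && has("Aromatic", -3L) && has("Pro", 2L)) {
      mode <- "II"
    } else if (i - 3L >= 1L && i + 2L <= n &&
               has("Arg", -3L) && has("Pro", 2L)) {
      mode <- "I"
    } else if (i == n - 1L && p$c_terminus == "free-acid") {
      mode <- "III"
    }
    data.frame(
      phospho_position = i,
      protein_position = p$protein_offset + i - 1L,
      residue = res[i],
      mode = mode,
      stringsAsFactors = FALSE
    ) -> row
    row$anchors <- list(anchors)
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(phospho_position = integer(0),
                      protein_position = integer(0),
                      residue = character(0), mode = character(0),
                      stringsAsFactors = FALSE)
    out$anchors <- list()
  }
  rownames(out) <- NULL
  out
}
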