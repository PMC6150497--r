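# Degenerate promoter-motif scan with a cross-species conservation rule:
# promoter sequences (5'->3', ending at the translation start) are scanned
# for a degenerate binding motif given in brace notation, e.g. the
# KLF4-type motif {G/A}{G/A}GG{C/T}G{C/T}; a hit is "conserved" when every
# species carries an exact hit at closely matching upstream positions.

IUPAC_BY_SET <- c(A = "A", C = "C", G = "G", T = "T",
                  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S",
                  "CT" = "Y", "GT" = "K", "ACG" = "V", "ACT" = "H",
                  "AGT" = "D", "CGT" = "B", "ACGT" = "N")

#' Parse a degenerate motif from brace notation
#'
#' Accepts plain bases and brace groups like `{G/A}`; e.g.
#' `"{G/A}{G/A}GG{C/T}G{C/T}"` is a 7-position motif.
#'
#' @param pattern motif string.
#' @return object of class `motif_spec`: list `positions` (character
#'   vectors of allowed bases), `length`, `iupac` (equivalent IUPAC string).
#' @export
motif_spec <- function(pattern) {
  chars <- strsplit(gsub("\\s", "", pattern), "")[[1]]
  positions <- list()
  i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "{") {
      j <- i
      while (j <= length(chars) && chars[j] != "}") j <- j + 1
      if (j > length(chars)) stop("unbalanced '{' in motif")
      inner <- paste(chars[(i + 1):(j - 1)], collapse = "")
      bases <- toupper(strsplit(inner, "/", fixed = TRUE)[[1]])
      i <- j + 1
    } else {
      bases <- toupper(chars[i])
      i <- i + 1
    }
    if (!length(bases) || !all(bases %in% c("A", "C", "G", "T")))
      stop("motif position with invalid base set: ",
           paste(bases, collapse = "/"))
    positions[[length(positions) + 1]] <- sort(unique(bases))
  }
  if (!length(positions)) stop("empty motif")
  iupac <- paste(vapply(positions, function(b)
    IUPAC_BY_SET[[paste(b, collapse = "")]], character(1)), collapse = "")
  structure(list(positions = positions, length = length(positions),
                 iupac = iupac, pattern = pattern),
            class = "motif_spec")
}

#' Enumerate all concrete k-mers matching a degenerate motif
#'
#' @param motif a [motif_spec()] or a brace-notation string.
#' @return character vector of all matching k-mers (lexicographic order).
#' @export
motif_expand <- function(motif) {
  if (is.character(motif)) motif <- motif_spec(motif)
  grid <- do.call(expand.grid,
                  c(rev(motif$positions), stringsAsFactors = FALSE))
  sort(apply(grid[, rev(seq_len(motif$length)), drop = FALSE], 1, paste,
             collapse = ""))
}

#' Scan promoter sequences for a degenerate motif, with conservation calls
#'
#' Sequences are promoter regions oriented 5'->3' and ending at the
#' translation start, one per species; positions are reported relative to
#' the start (negative = upstream; a hit occupying the last `L` bases is at
#' position `-L`). Only the last `window` bases are scanned. Exact
#' (degenerate) hits in every species that lie within `conserved_start_max`
#' of the start and within `conserved_pos_tol` of a hit in every other
#' species are classed `conserved`; hits differing from the motif at
#' exactly one position are reported as `near-match` (never conserved);
#' remaining exact hits are `unclassified`.
#'
#' @param promoters a named [Biostrings::DNAStringSet], a named character
#'   vector of sequences, or a FASTA path (names = species).
#' @param motif a [motif_spec()] or brace-notation string.
#' @param window upstream bases scanned (default 10000).
#' @param conserved_pos_tol maximum cross-species position difference for a
#'   conserved call (default 100).
#' @param conserved_start_max maximum distance from the translation start
#'   for a conserved call (default 1000).
#' @return data.frame of hits: `species`, `position`, `match`, `class`.
#' @export
motif_scan <- function(promoters, motif, window = 10000,
                       conserved_pos_tol = 100,
                       conserved_start_max = 1000) {
  if (is.character(motif)) motif <- motif_spec(motif)
  if (is.character(promoters) && length(promoters) == 1 &&
      file.exists(promoters))
    promoters <- Biostrings::readDNAStringSet(promoters)
  if (is.character(promoters))
    promoters <- Biostrings::DNAStringSet(toupper(promoters))
  if (is.null(names(promoters)) || any(!nzchar(names(promoters))))
    stop("promoter sequences must be named by species")
  pat <- Biostrings::DNAString(motif$iupac)
  hits <- lapply(names(promoters), function(sp) {
    seqall <- promoters[[sp]]
    if (length(seqall) < motif$length)
      return(data.frame(species = character(), position = integer(),
                        match = character(), mismatches = integer()))
    offset <- max(0L, length(seqall) - window)
    seq <- Biostrings::subseq(seqall, offset + 1L)
    letters_present <- unique(strsplit(as.character(seq), "")[[1]])
    if (any(!letters_present %in% c("A", "C", "G", "T")))
      warning("species '", sp, "': non-ACGT characters present; ",
              "they match no motif position")
    near <- Biostrings::matchPattern(pat, seq, max.mismatch = 1,
                                     fixed = "subject")
    # mismatch-tolerant matching can return views hanging over the
    # sequence ends; only fully contained windows are real hits
    inb <- Biostrings::start(near) >= 1 &
      Biostrings::end(near) <= length(seq)
    near <- near[inb]
    if (!length(near))
      return(data.frame(species = character(), position = integer(),
                        match = character(), mismatches = integer()))
    starts <- Biostrings::start(near)
    mm <- vapply(seq_along(near), function(i) {
      kmer <- strsplit(as.character(near[[i]]), "")[[1]]
      sum(vapply(seq_along(kmer), function(p)
        !(kmer[p] %in% motif$positions[[p]]), logical(1)))
    }, integer(1))
    keep <- mm <= 1
    data.frame(species = sp,
               position = starts[keep] + offset - length(seqall) - 1L,
               match = vapply(which(keep), function(i)
                 as.character(near[[i]]), character(1)),
               mismatches = mm[keep], stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits))
    return(data.frame(species = character(), position = integer(),
                      match = character(), class = character()))
  hits$class <- ifelse(hits$mismatches == 1, "near-match", "unclassified")
  species <- unique(hits$species)
  exact <- hits[hits$mismatches == 0, , drop = FALSE]
  cand <- exact[abs(exact$position) <= conserved_start_max, , drop = FALSE]
  if (length(species) >= 2 &&
      length(unique(cand$species)) == length(species)) {
    # one candidate hit per species, all pairwise position gaps within tol
    pos_by_sp <- split(cand$position, cand$species)
    combos <- do.call(expand.grid, pos_by_sp)
    ok <- apply(combos, 1, function(p) max(p) - min(p) <= conserved_pos_tol)
    for (ci in which(ok)) {
      for (sp in names(pos_by_sp)) {
        hits$class[hits$species == sp &
                   hits$position == combos[ci, sp] &
                   hits$mismatches == 0] <- "conserved"
      }
    }
  }
  hits$mismatches <- NULL
  rownames(hits) <- NULL
  hits[order(hits$species, hits$position), , drop = FALSE]
}
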