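#' Parse transgene sequences from FASTA
#'
#' `readTransgeneFasta` reads a FASTA file; `parseTransgeneFasta` parses
#' FASTA-formatted text already in memory. The token before the first
#' whitespace of each header becomes the transgene name; sequence lines
#' are concatenated and uppercased. Entry order is preserved.
#'
#' @param file Path to a FASTA file.
#' @param text A single string (or character vector of lines) of
#'   FASTA-formatted text.
#' @param ... Passed on to [TransgeneRegistry()] (e.g.
#'   `projectionTarget`).
#'
#' @return A [TransgeneRegistry-class].
#' @examples
#' parseTransgeneFasta(">t1 some description\nACGT\nACGT\n>t2\nGGGG")
#' @export
parseTransgeneFasta <- function(text, ...) {
    f <- tempfile(fileext = ".fa")
    on.exit(unlink(f))
    writeLines(paste(text, collapse = "\n"), f)
    readTransgeneFasta(f, ...)
}

#' @rdname parseTransgeneFasta
#' @export
readTransgeneFasta <- function(file, ...) {
    seqs <- Biostrings::readBStringSet(file)
    if (length(seqs) == 0L)
        stop("FASTA contains no entries")
    nm <- sub("\\s.*$", "", names(seqs))
    if (any(!nzchar(nm)))
        stop("FASTA headers must be nonempty")
    if (anyDuplicated(nm))
        stop(sprintf("duplicate transgene name(s) in FASTA: %s",
            paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (any(Biostrings::width(seqs) == 0L))
        stop(sprintf("empty sequence for entry: %s",
            paste(nm[Biostrings::width(seqs) == 0L], collapse = ", ")))
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
    names(seqs) <- nm
    TransgeneRegistry(seqs, ...)
}

#' Emit a transgene-augmented reference
#'
#' Produces the FASTA and GTF text that appends each transgene as an
#' extra contig to a genome reference, so that an external aligner
#' (e.g. a CellRanger-style pipeline) quantifies viral barcodes alongside
#' endogenous genes. Each transgene becomes one contig named by the
#' record name, annotated by gene/transcript/exon GTF lines spanning
#' positions 1..length (1-based, closed, strand `+`) with
#' `gene_id`/`transcript_id` equal to the name. Output is byte-stable
#' for a given registry.
#'
#' @param registry A nonempty [TransgeneRegistry-class].
#' @param fasta,gtf Output file paths for `writeAugmentedReference`.
#' @param width Line width for FASTA wrapping (default 60).
#'
#' @return `augmentedReference` returns `list(fasta =, gtf =)`, each a
#'   single string. `writeAugmentedReference` writes both files and
#'   returns their paths invisibly.
#' @examples
#' reg <- TransgeneRegistry(c(t1 = "ACGT"))
#' cat(augmentedReference(reg)$gtf)
#' @export
augmentedReference <- function(registry, width = 60L) {
    stopifnot(is(registry, "TransgeneRegistry"))
    if (length(registry) == 0L)
        stop("cannot augment a reference from an empty registry")
    seqs <- as.character(registry@sequences)
    nm <- names(registry)
    fastaLines <- unlist(lapply(seq_along(seqs), function(i) {
        s <- seqs[[i]]
        starts <- seq(1L, nchar(s), by = width)
        c(paste0(">", nm[i]),
          substring(s, starts, pmin(starts + width - 1L, nchar(s))))
    }))
    len <- nchar(seqs)
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', nm, nm)
    gtfLines <- unlist(lapply(seq_along(nm), function(i) {
        sprintf("%s\ttransgene_overlay\t%s\t1\t%d\t.\t+\t.\t%s",
            nm[i], c("gene", "transcript", "exon"), len[i], attrs[i])
    }))
    list(fasta = paste0(paste(fastaLines, collapse = "\n"), "\n"),
         gtf = paste0(paste(gtfLines, collapse = "\n"), "\n"))
}

#' @rdname augmentedReference
#' @export
writeAugmentedReference <- function(registry, fasta, gtf, width = 60L) {
    ref <- augmentedReference(registry, width = width)
    writeChar(ref$fasta, fasta, eos = NULL)
    writeChar(ref$gtf, gtf, eos = NULL)
    invisible(c(fasta = fasta, gtf = gtf))
}

# substitution matrix over A/C/G/T/N: +1 exact base match, -1 otherwise;
# N is never a match, even against N.
.identityScoreMatrix <- function() {
    letters <- c("A", "C", "G", "T", "N")
    m <- matrix(-1, 5, 5, dimnames = list(letters, letters))
    diag(m)[1:4] <- 1
    m
}

.kmerSet <- function(s, k) {
    n <- nchar(s)
    if (k > n) return(character(0))
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Global-alignment identity between two transgene sequences
#'
#' Quantifies how discriminable two (possibly homologous) transgene
#' barcodes are. Percent identity is computed from a global
#' Needleman-Wunsch alignment with match +1, mismatch -1, and linear gap
#' penalty -2 per gap position, as
#' `100 * matches / alignment_length`; `N` never counts as a match. The
#' shared k-mer fraction is the Jaccard similarity of the two k-mer sets
#' and approximates the probability that a read-length subsequence fails
#' to discriminate the pair.
#'
#' @param a,b Sequences: character strings, [Biostrings::DNAString]s, or
#'   a [TransgeneRegistry-class] plus two names.
#' @param k k-mer length for the shared-fraction computation (default 90,
#'   on the order of a sequencing read).
#'
#' @return A list with elements `pair`, `percentIdentity`,
#'   `alignedLength`, and `sharedKmerFraction`.
#' @examples
#' pairwiseIdentity("ACGTACGT", "ACGTTCGT", k = 4)
#' @export
pairwiseIdentity <- function(a, b, k = 90L) {
    nmA <- "a"; nmB <- "b"
    if (is(a, "TransgeneRegistry")) {
        stopifnot(is.character(b), length(b) == 2L)
        nmA <- b[1]; nmB <- b[2]
        sa <- as.character(a@sequences[[nmA]])
        sb <- as.character(a@sequences[[nmB]])
    } else {
        sa <- toupper(as.character(a)); sb <- toupper(as.character(b))
    }
    if (!nzchar(sa) || !nzchar(sb))
        stop("sequences must be nonempty")
    al <- Biostrings::pairwiseAlignment(sa, sb, type = "global",
        substitutionMatrix = .identityScoreMatrix(),
        gapOpening = 0, gapExtension = 2)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    matches <- sum(pa == ps & pa != "N" & pa != "-")
    alen <- length(pa)
    ka <- .kmerSet(sa, k); kb <- .kmerSet(sb, k)
    shared <- if (length(ka) == 0L && length(kb) == 0L) NA_real_ else
        length(intersect(ka, kb)) / length(union(ka, kb))
    list(pair = c(nmA, nmB),
         percentIdentity = 100 * matches / alen,
         alignedLength = alen,
         sharedKmerFraction = shared)
}

#' Pairwise discriminability report for a registry
#'
#' Computes [pairwiseIdentity()] for every unordered pair of transgenes
#' and flags pairs that share any k-mer at read-length scale: such pairs
#' can generate reads that align ambiguously, so their barcodes are not
#' safely discriminable.
#'
#' @param registry A [TransgeneRegistry-class] with at least two records.
#' @param k k-mer length; must not exceed the shortest sequence.
#'
#' @return A [S4Vectors::DataFrame] with one row per unordered pair:
#'   `name1`, `name2`, `percentIdentity`, `alignedLength`,
#'   `sharedKmerFraction`, `warn`.
#' @export
discriminabilityReport <- function(registry, k = 90L) {
    stopifnot(is(registry, "TransgeneRegistry"))
    if (length(registry) < 2L)
        stop("discriminability requires at least two transgenes")
    if (k > min(Biostrings::width(registry@sequences)))
        stop(sprintf("k = %d exceeds the shortest sequence (%d)",
            k, min(Biostrings::width(registry@sequences))))
    nm <- names(registry)
    pairs <- utils::combn(nm, 2)
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
        r <- pairwiseIdentity(registry, pairs[, j], k = k)
        DataFrame(name1 = r$pair[1], name2 = r$pair[2],
            percentIdentity = r$percentIdentity,
            alignedLength = r$alignedLength,
            sharedKmerFraction = r$sharedKmerFraction,
            warn = r$sharedKmerFraction > 0)
    })
    do.call(rbind, rows)
}
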