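# Readers, writers and validation for the external data formats: trio codon
# alignments (FASTA), protein domain-architecture tables (TSV),
# spatio-temporal expression tables (TSV) and the 3-leaf analysis tree
# (newick).

#' Construct a validated duplicate-trio codon alignment
#'
#' A `codon_trio` holds the aligned, in-frame coding sequences of the two
#' duplicate gene copies and the outgroup ortholog for one duplicate pair.
#' All three sequences must have equal length divisible by three, over the
#' alphabet `A,C,G,T,N,-`. Codon columns containing a gap or `N` in any
#' sequence are masked from every downstream computation; after masking no
#' sequence may contain an internal stop codon (a stop in the final column
#' is tolerated and masked).
#'
#' @param pair_id Identifier for the duplicate pair.
#' @param copy1,copy2,outgroup Aligned nucleotide strings.
#' @return An object of class `codon_trio` with fields `pair_id`, `copy1`,
#'   `copy2`, `outgroup` and `n_columns` (codon-column count).
#' @examples
#' codon_trio("pair1", "ATGTTT", "ATGTTC", "ATGTTT")
#' @export
codon_trio <- function(pair_id, copy1, copy2, outgroup) {
  seqs <- c(copy1 = copy1, copy2 = copy2, outgroup = outgroup)
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop_typed("trio_length_mismatch",
               sprintf("sequence lengths differ: %s",
                       paste(lens, collapse = ", ")))
  }
  if (lens[1] %% 3L != 0L) {
    stop_typed("trio_frame_error",
               sprintf("alignment length %d is not divisible by 3", lens[1]))
  }
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop_typed("trio_alphabet_error",
               sprintf("invalid characters in sequence(s): %s",
                       paste(names(seqs)[bad], collapse = ", ")))
  }
  obj <- structure(
    list(pair_id = as.character(pair_id),
         copy1 = unname(seqs[["copy1"]]),
         copy2 = unname(seqs[["copy2"]]),
         outgroup = unname(seqs[["outgroup"]]),
         n_columns = as.integer(lens[1] %/% 3L)),
    class = "codon_trio")
  .check_internal_stops(obj)
  obj
}

# Stop with a classed condition so tests can assert on error type.
stop_typed <- function(class, message) {
  stop(structure(class = c(class, "dupasym_error", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}

# Codon index matrix (n_columns x 3) with NA at masked columns.
# Masked: any gap or N in the codon of any sequence, plus stop codons
# (only tolerated in the final column).
.trio_indices <- function(trio) {
  cd <- codon_data()
  m <- sapply(c("copy1", "copy2", "outgroup"), function(role) {
    cods <- .codon_split(trio[[role]])
    idx <- cd$index[cods]
    unname(idx)
  })
  if (trio$n_columns == 1L) m <- matrix(m, nrow = 1L,
                                        dimnames = list(NULL, c("copy1", "copy2", "outgroup")))
  masked <- rowSums(is.na(m)) > 0L
  m[masked, ] <- NA_integer_
  m
}

.check_internal_stops <- function(trio) {
  cd <- codon_data()
  for (role in c("copy1", "copy2", "outgroup")) {
    cods <- .codon_split(trio[[role]])
    clean <- !grepl("[-N]", cods)
    is_stop <- clean & cods %in% cd$stops
    internal <- which(is_stop & seq_along(cods) < length(cods))
    if (length(internal)) {
      stop_typed("trio_stop_codon",
                 sprintf("internal stop codon in %s at codon column %d",
                         role, internal[1]))
    }
  }
  invisible(trio)
}

#' @export
print.codon_trio <- function(x, ...) {
  cat(sprintf("codon_trio '%s': %d codon columns\n", x$pair_id, x$n_columns))
  invisible(x)
}

#' Read a duplicate-trio codon alignment from FASTA
#'
#' The FASTA file must contain exactly three aligned records whose ids carry
#' role tags identifying the two duplicate copies and the outgroup. By
#' default a record belongs to a role when its id contains the substring
#' `|copy1`, `|copy2` or `|outgroup`; pass `roles` to change the convention.
#'
#' @param path Path to an aligned FASTA file.
#' @param pair_id Pair identifier; defaults to the file name without
#'   extension.
#' @param roles Named character vector mapping roles `copy1`, `copy2`,
#'   `outgroup` to the id substrings that tag them.
#' @return A validated [codon_trio()].
#' @export
read_trio_fasta <- function(path, pair_id = NULL,
                            roles = c(copy1 = "|copy1", copy2 = "|copy2",
                                      outgroup = "|outgroup")) {
  stopifnot(all(c("copy1", "copy2", "outgroup") %in% names(roles)))
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 3L) {
    stop_typed("trio_record_count",
               sprintf("expected 3 records, found %d in %s",
                       length(recs), path))
  }
  ids <- names(recs)
  assign_role <- function(role) {
    hit <- which(grepl(roles[[role]], ids, fixed = TRUE))
    if (length(hit) != 1L) {
      stop_typed("trio_role_error",
                 sprintf("role tag '%s' matches %d records (need exactly 1)",
                         roles[[role]], length(hit)))
    }
    as.character(recs[[hit]])
  }
  if (is.null(pair_id)) pair_id <- sub("\\.[^.]*$", "", basename(path))
  codon_trio(pair_id,
             copy1 = assign_role("copy1"),
             copy2 = assign_role("copy2"),
             outgroup = assign_role("outgroup"))
}

#' Write a trio alignment to FASTA
#'
#' @param trio A [codon_trio()].
#' @param path Output file path.
#' @param roles Role-tag convention, as in [read_trio_fasta()].
#' @return `path`, invisibly.
#' @export
write_trio_fasta <- function(trio, path,
                             roles = c(copy1 = "|copy1", copy2 = "|copy2",
                                       outgroup = "|outgroup")) {
  lines <- character(0)
  for (role in c("copy1", "copy2", "outgroup")) {
    lines <- c(lines, paste0(">", trio$pair_id, roles[[role]]), trio[[role]])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a protein domain architecture
#'
#' Ordered, non-overlapping amino-acid intervals naming Pfam-style domains on
#' one protein, 1-based inclusive coordinates on the aligned protein.
#'
#' @param protein_id Protein identifier.
#' @param domain_name Character vector of domain names.
#' @param start_aa,end_aa Integer vectors of interval bounds.
#' @return An object of class `domain_architecture` with fields `protein_id`
#'   and `intervals` (data frame, sorted by `start_aa`).
#' @export
domain_architecture <- function(protein_id, domain_name, start_aa, end_aa) {
  start_aa <- .as_strict_integer(start_aa, "start_aa")
  end_aa <- .as_strict_integer(end_aa, "end_aa")
  stopifnot(length(domain_name) == length(start_aa),
            length(start_aa) == length(end_aa))
  if (any(start_aa < 1L)) {
    stop_typed("domain_coordinate_error", "start_aa must be >= 1")
  }
  if (any(start_aa > end_aa)) {
    stop_typed("domain_coordinate_error", "start_aa > end_aa")
  }
  iv <- data.frame(domain_name = as.character(domain_name),
                   start_aa = start_aa, end_aa = end_aa,
                   stringsAsFactors = FALSE)
  iv <- iv[order(iv$start_aa, iv$end_aa), , drop = FALSE]
  rownames(iv) <- NULL
  if (nrow(iv) > 1L && any(iv$start_aa[-1L] <= iv$end_aa[-nrow(iv)])) {
    stop_typed("domain_overlap_error",
               sprintf("overlapping domain intervals for protein %s",
                       protein_id))
  }
  structure(list(protein_id = as.character(protein_id), intervals = iv),
            class = "domain_architecture")
}

.as_strict_integer <- function(x, what) {
  xi <- suppressWarnings(as.numeric(x))
  if (anyNA(xi) || any(xi != round(xi))) {
    stop_typed("domain_coordinate_error",
               sprintf("non-integer %s value", what))
  }
  as.integer(xi)
}

#' @export
print.domain_architecture <- function(x, ...) {
  cat(sprintf("domain_architecture '%s': %d domain(s) [%s]\n", x$protein_id,
              nrow(x$intervals), paste(x$intervals$domain_name, collapse = ", ")))
  invisible(x)
}

#' Read a domain-architecture table
#'
#' Expects a tab-separated file with a header row and columns `protein_id`,
#' `domain_name`, `start_aa`, `end_aa`.
#'
#' @param path Path to the TSV file.
#' @return Named list of [domain_architecture()] objects (one per protein;
#'   empty list for an empty file).
#' @export
read_domain_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "domain_name", "start_aa", "end_aa")
  if (!all(need %in% names(df))) {
    stop_typed("domain_table_error",
               sprintf("missing column(s): %s",
                       paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if (nrow(df) == 0L) return(stats::setNames(list(), character(0)))
  out <- lapply(split(df, df$protein_id), function(d) {
    domain_architecture(d$protein_id[1], d$domain_name, d$start_aa, d$end_aa)
  })
  out[unique(df$protein_id)]
}

#' Write domain architectures to a TSV table
#'
#' @param archs List of [domain_architecture()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(archs, path) {
  rows <- lapply(archs, function(a) {
    cbind(protein_id = a$protein_id, a$intervals)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(protein_id = character(0), domain_name = character(0),
                     start_aa = integer(0), end_aa = integer(0))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Are three domain architectures identical?
#'
#' Architectures count as identical when the ordered sequences of domain
#' names agree across all three proteins; coordinates may differ. This mirrors
#' the admission rule that duplicates and outgroup must share the same
#' domain architecture.
#'
#' @param a1,a2,a3 [domain_architecture()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
architectures_identical <- function(a1, a2, a3) {
  n1 <- a1$intervals$domain_name
  n2 <- a2$intervals$domain_name
  n3 <- a3$intervals$domain_name
  identical(n1, n2) && identical(n2, n3)
}

#' Construct a spatio-temporal expression profile
#'
#' @param gene_id Gene identifier.
#' @param stages Named list mapping developmental-stage labels to non-empty
#'   character vectors of anatomy-term identifiers.
#' @return An object of class `expression_profile`.
#' @export
expression_profile <- function(gene_id, stages) {
  stopifnot(is.list(stages), !is.null(names(stages)))
  stages <- lapply(stages, function(x) sort(unique(as.character(x))))
  if (any(lengths(stages) == 0L)) {
    stop_typed("expression_empty_stage",
               sprintf("gene %s has a stage with no anatomy terms", gene_id))
  }
  structure(list(gene_id = as.character(gene_id), stages = stages),
            class = "expression_profile")
}

#' Read a spatio-temporal expression table
#'
#' Tab-separated file with header and columns `gene_id`, `stage`,
#' `anatomy_term` (one term per row). Duplicate rows collapse under set
#' semantics.
#'
#' @param path Path to the TSV file.
#' @return Named list of [expression_profile()] objects.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "stage", "anatomy_term")
  if (!all(need %in% names(df))) {
    stop_typed("expression_table_error",
               sprintf("missing column(s): %s",
                       paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if (anyNA(df[need]) || any(df$anatomy_term == "")) {
    stop_typed("expression_table_error", "malformed row (empty field)")
  }
  if (nrow(df) == 0L) return(stats::setNames(list(), character(0)))
  out <- lapply(split(df, df$gene_id), function(d) {
    expression_profile(d$gene_id[1], split(d$anatomy_term, d$stage))
  })
  out[unique(df$gene_id)]
}

#' Write expression profiles to a TSV table
#'
#' @param profiles List of [expression_profile()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    do.call(rbind, lapply(names(p$stages), function(s) {
      data.frame(gene_id = p$gene_id, stage = s,
                 anatomy_term = p$stages[[s]], stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(gene_id = character(0), stage = character(0),
                     anatomy_term = character(0))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The unrooted duplicate-trio tree
#'
#' Returns the fixed 3-leaf unrooted tree relating the two duplicate copies
#' and the outgroup ortholog, as an `ape` `phylo` object, with the supplied
#' branch lengths (expected substitutions per codon).
#'
#' @param t_by_branch Named numeric vector with entries `copy1`, `copy2`,
#'   `outgroup`.
#' @return An `ape::phylo` tree with three tips.
#' @export
trio_tree <- function(t_by_branch = c(copy1 = 1, copy2 = 1, outgroup = 1)) {
  stopifnot(all(c("copy1", "copy2", "outgroup") %in% names(t_by_branch)),
            all(t_by_branch >= 0))
  txt <- sprintf("(copy1:%g,copy2:%g,outgroup:%g);",
                 t_by_branch[["copy1"]], t_by_branch[["copy2"]],
                 t_by_branch[["outgroup"]])
  ape::read.tree(text = txt)
}

#' Read the trio tree from a newick file
#'
#' @param path Path to a newick file containing one 3-leaf tree with tip
#'   labels `copy1`, `copy2`, `outgroup` and branch lengths.
#' @return Named numeric vector of branch lengths by role.
#' @export
read_trio_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr) || length(tr$tip.label) != 3L) {
    stop_typed("tree_error", "expected a single 3-leaf newick tree")
  }
  need <- c("copy1", "copy2", "outgroup")
  if (!all(need %in% tr$tip.label)) {
    stop_typed("tree_error",
               "tip labels must be copy1, copy2, outgroup")
  }
  el <- tr$edge.length[match(match(need, tr$tip.label), tr$edge[, 2])]
  stats::setNames(el, need)
}
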