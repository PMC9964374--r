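#' Read protein sequences from a FASTA file
#'
#' Parses a (plain or multi-line) FASTA file into a protein-record table.
#' Sequences are upper-cased on ingest; trailing or internal `*` stop
#' characters are stripped with a warning (Ensembl protein exports may
#' include them). The 20 standard residues plus the ambiguity letters
#' X, B, Z and U are accepted; anything else is an error reported with
#' its record and position.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `id`, `description` and `sequence`,
#'   one row per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  protein_set(ids, desc, seqs)
}

# Validate and assemble a protein-record table.
protein_set <- function(ids, descriptions, sequences) {
  if (any(!nzchar(ids))) stop("empty sequence identifier")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(grepl("\\*", sequences))) {
    warning("'*' stop characters stripped from ",
            sum(grepl("\\*", sequences)), " sequence(s)")
    sequences <- gsub("\\*", "", sequences)
  }
  empty <- !nzchar(sequences)
  if (any(empty)) {
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "))
  }
  allowed <- c(AA_STANDARD, AA_AMBIGUOUS)
  for (i in seq_along(sequences)) {
    chars <- strsplit(sequences[i], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% allowed)
    if (length(bad) > 0L) {
      stop("invalid residue '", chars[bad[1]], "' at position ", bad[1],
           " in record ", ids[i])
    }
  }
  data.frame(id = ids, description = descriptions, sequence = sequences,
             stringsAsFactors = FALSE)
}

#' Write a protein-record table to FASTA
#'
#' @param records Data frame with columns `id`, `description`, `sequence`.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    if (!is.null(records$description) && nzchar(records$description[i])) {
      hdr <- paste(hdr, records$description[i])
    }
    writeLines(paste0(">", hdr), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' All sequences must have the same (gapped) length; `-` is the gap
#' character.
#'
#' @param path Path to an aligned FASTA file.
#' @return An object of class `aa_alignment`: a list with `ids`,
#'   `sequences` (gapped, upper case) and `n_columns`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  aa_alignment(ids, seqs)
}

#' Construct an alignment object from gapped sequences
#'
#' @param ids Character vector of sequence identifiers.
#' @param sequences Equal-length gapped sequences (`-` for gaps).
#' @return An `aa_alignment` object.
#' @export
aa_alignment <- function(ids, sequences) {
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences have unequal lengths: ",
         paste(unique(lens), collapse = ", "))
  }
  if (lens[1] < 1L) stop("alignment has zero columns")
  structure(list(ids = ids, sequences = unname(sequences),
                 n_columns = unname(lens[1])),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("aa_alignment:", length(x$ids), "sequences x", x$n_columns,
      "columns\n")
  invisible(x)
}

#' Read a TSV table with a required-column contract
#'
#' Reads a tab-separated file with a header row and checks that the named
#' columns are present; columns listed in `numeric_columns` are parsed as
#' numbers, with an error naming the first offending row and column.
#'
#' @param path Path to a TSV file.
#' @param required_columns Character vector of column names that must exist.
#' @param numeric_columns Subset of columns that must parse as numeric.
#' @return A `data.frame`.
#' @export
read_table <- function(path, required_columns = character(),
                       numeric_columns = character()) {
  if (!file.exists(path)) stop("table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  missing <- setdiff(required_columns, names(df))
  if (length(missing) > 0L) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  for (col in numeric_columns) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad) > 0L) {
      stop("unparseable numeric value in column '", col, "', row ", bad[1],
           ": '", df[[col]][bad[1]], "'")
    }
    df[[col]] <- vals
  }
  df
}

#' Write a data frame as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read backbone geometry and per-residue confidence from a PDB file
#'
#' Parses fixed-column PDB v3.3 `ATOM` records (first model, first
#' alternate location only) and retains the N, CA and C backbone atoms of
#' each residue together with the B-factor-field value of its CA (the
#' per-residue confidence convention of predicted structures, e.g. pLDDT).
#' Residues missing any backbone atom are kept but flagged incomplete.
#'
#' @param path Path to a PDB file.
#' @return An object of class `pdb_backbone`: a list with `residues`
#'   (data.frame: chain, resno, resname, confidence, complete) and
#'   `coords`, a `n x 3 x 3` array indexed residue x atom (N, CA, C) x
#'   coordinate (x, y, z) in Angstrom.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path)
  atom <- lines[startsWith(lines, "ATOM  ")]
  # first model only
  end1 <- which(startsWith(lines, "ENDMDL"))
  if (length(end1) > 0L) {
    atom <- lines[startsWith(lines, "ATOM  ") & seq_along(lines) < end1[1]]
  }
  if (length(atom) == 0L) stop("no ATOM records in ", path)
  name <- trimws(substr(atom, 13, 16))
  altloc <- substr(atom, 17, 17)
  keep <- altloc %in% c(" ", "A") & name %in% c("N", "CA", "C")
  atom <- atom[keep]; name <- name[keep]
  if (length(atom) == 0L) stop("no backbone ATOM records in ", path)
  chain <- substr(atom, 22, 22)
  resno <- suppressWarnings(as.integer(substr(atom, 23, 26)))
  resname <- trimws(substr(atom, 18, 20))
  x <- suppressWarnings(as.numeric(substr(atom, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(atom, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(atom, 47, 54)))
  bfac <- suppressWarnings(as.numeric(substr(atom, 61, 66)))
  if (anyNA(resno) || anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("malformed fixed-width ATOM record in ", path)
  }
  key <- paste(chain, resno)
  ukey <- unique(key)
  n <- length(ukey)
  coords <- array(NA_real_, dim = c(n, 3, 3),
                  dimnames = list(NULL, c("N", "CA", "C"),
                                  c("x", "y", "z")))
  res <- data.frame(chain = character(n), resno = integer(n),
                    resname = character(n), confidence = NA_real_,
                    complete = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sel <- which(key == ukey[i])
    res$chain[i] <- chain[sel[1]]
    res$resno[i] <- resno[sel[1]]
    res$resname[i] <- resname[sel[1]]
    for (j in sel) {
      coords[i, name[j], ] <- c(x[j], y[j], z[j])
      if (name[j] == "CA") res$confidence[i] <- bfac[j]
    }
    res$complete[i] <- !anyNA(coords[i, , ])
  }
  # residue numbers must increase within a chain
  for (ch in unique(res$chain)) {
    rn <- res$resno[res$chain == ch]
    if (any(diff(rn) <= 0)) {
      stop("residue numbers not strictly increasing in chain ", ch)
    }
  }
  structure(list(residues = res, coords = coords), class = "pdb_backbone")
}

#' @export
print.pdb_backbone <- function(x, ...) {
  cat("pdb_backbone:", nrow(x$residues), "residues,",
      sum(!x$residues$complete), "incomplete\n")
  invisible(x)
}

#' Write a backbone structure as a PDB file
#'
#' Emits fixed-column `ATOM` records for the N, CA and C atoms, with the
#' per-residue confidence value in the B-factor field. Intended for
#' synthetic structures built by [generate_helix_structure()].
#'
#' @param structure A `pdb_backbone` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  res <- structure$residues
  coords <- structure$coords
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (i in seq_len(nrow(res))) {
    for (atm in c("N", "CA", "C")) {
      xyz <- coords[i, atm, ]
      if (anyNA(xyz)) next
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d %-4s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        serial, paste0(" ", atm), res$resname[i], res$chain[i],
        res$resno[i], xyz[1], xyz[2], xyz[3], 1.00,
        ifelse(is.na(res$confidence[i]), 0, res$confidence[i])), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}
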