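# Low-level chemistry layer. All molecule handling is delegated to Open Babel
# through the obabel executable; this file wraps it behind vectorized helpers
# that track per-molecule failures by title.

ob_binary <- function() {
  path <- Sys.which("obabel")
  if (!nzchar(path)) stop("the 'obabel' executable was not found on PATH")
  path
}

# Run obabel on a set of SMILES, one per line, titles "s<i>".
# Returns the raw output lines; molecules obabel cannot parse are absent.
ob_run <- function(smiles, out_format, extra_args = character()) {
  stopifnot(is.character(smiles))
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = paste0(".", out_format))
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles, paste0("s", seq_along(smiles))), fin)
  system2(ob_binary(), c(fin, "-e", paste0("-o", out_format), "-O", fout, extra_args),
          stdout = FALSE, stderr = FALSE)
  if (!file.exists(fout)) character(0) else readLines(fout, warn = FALSE)
}

# Parse "SMILES\ts<i>[ appended...]" lines into a character vector aligned with
# the input (NA where obabel dropped the molecule).
ob_align <- function(lines, n) {
  out <- rep(NA_character_, n)
  extras <- vector("list", n)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) next
    title_fields <- strsplit(trimws(parts[2]), " +")[[1]]
    idx <- suppressWarnings(as.integer(sub("^s", "", title_fields[1])))
    if (is.na(idx) || idx < 1L || idx > n) next
    out[idx] <- parts[1]
    if (length(title_fields) > 1L) {
      extras[[idx]] <- suppressWarnings(as.numeric(title_fields[-1]))
    }
  }
  structure(out, extras = extras)
}

#' Standardize compound structures
#'
#' Applies the standardization convention used throughout the pipeline:
#' keep the largest fragment (salt stripping), apply a pH 7.0
#' (de)protonation model, neutralize remaining +1/-1 charges, and emit the
#' canonical SMILES of the resulting neutral parent. The operation is
#' idempotent: standardizing an already standardized SMILES returns it
#' unchanged.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` for molecules that
#'   could not be parsed, with a `"reason"` attribute (character vector,
#'   `NA` where parsing succeeded).
#' @examples
#' \dontrun{
#' standardize_compound(c("CCN.Cl", "CC(=O)[O-].[Na+]"))
#' }
#' @export
standardize_compound <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(structure(character(0), reason = character(0)))
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  bad <- is.na(smiles) | !nzchar(smiles) | grepl("[[:space:]]", smiles)
  reason[bad] <- "empty or whitespace-containing SMILES"
  ok <- which(!bad)
  if (length(ok)) {
    # pass 1: strip to largest fragment, protonation state at pH 7
    p1 <- ob_align(ob_run(smiles[ok], "smi", c("-r", "-p", "7")), length(ok))
    # pass 2: neutralize +-1 charges, canonical output
    live <- which(!is.na(p1))
    if (length(live)) {
      p2 <- ob_align(ob_run(p1[live], "can", "--neutralize"), length(live))
      out[ok[live]] <- as.character(p2)
    }
    reason[ok][is.na(out[ok])] <- "unparseable SMILES"
  }
  structure(out, reason = reason)
}

# Batch fingerprints through obabel's fpt writer (hex output). Returns a 0/1
# matrix with one row per input molecule; rows of NA where parsing failed.
ob_fingerprints <- function(smiles, type = "ECFP6", n_bits = 1024L) {
  n <- length(smiles)
  fp <- matrix(NA_integer_, n, n_bits)
  if (n == 0L) return(fp)
  lines <- ob_run(smiles, "fpt", c("-xh", "-xf", type, "-xN", n_bits))
  nibble <- matrix(0L, 16L, 4L) # hex digit -> 4 bits, most significant first
  for (v in 0:15) nibble[v + 1L, ] <- as.integer(bitwAnd(bitwShiftR(v, 3:0), 1L))
  cur <- NA_integer_
  buf <- character(0)
  flush <- function() {
    if (is.na(cur) || !length(buf)) return()
    hex <- strsplit(paste(buf, collapse = ""), "")[[1]]
    vals <- strtoi(hex, 16L)
    bits <- as.integer(t(nibble[vals + 1L, , drop = FALSE]))
    if (length(bits) == n_bits) fp[cur, ] <<- bits
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      title <- strsplit(trimws(sub("^>", "", ln)), "[[:space:]]+")[[1]][1]
      cur <- suppressWarnings(as.integer(sub("^s", "", title)))
      buf <- character(0)
    } else if (grepl("^[0-9a-fA-F ]+$", ln)) {
      buf <- c(buf, gsub(" ", "", ln))
    }
  }
  flush()
  fp
}

# Physicochemical property table through obabel descriptors plus graph counts.
# Columns: mw, logp, hbd, hba, rotatable_bonds, tpsa, ring_count, heavy_atoms.
ob_physchem <- function(smiles) {
  n <- length(smiles)
  props <- c("mw", "logp", "hbd", "hba", "rotatable_bonds", "tpsa",
             "ring_count", "heavy_atoms")
  out <- matrix(NA_real_, n, length(props), dimnames = list(NULL, props))
  if (n == 0L) return(out)
  lines <- ob_run(smiles, "smi",
                  c("--append", shQuote("MW logP HBD HBA1 rotors TPSA atoms bonds")))
  al <- ob_align(lines, n)
  ex <- attr(al, "extras")
  for (i in seq_len(n)) {
    v <- ex[[i]]
    if (is.null(v) || length(v) != 8L) next
    atoms <- v[7]; bonds <- v[8]
    # cyclomatic ring count; standardized input is a single fragment
    out[i, ] <- c(v[1], v[2], v[3], v[4], v[5], v[6],
                  max(bonds - atoms + 1, 0), atoms)
  }
  out
}
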