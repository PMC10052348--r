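# Compound and protein descriptor blocks, and their assembly into PCM
# feature matrices (compound blocks then protein blocks, no cross-terms).

#' Z-scale residue descriptors
#'
#' The five-dimensional Z-scales (principal properties of the 20 standard
#' amino acids derived from physicochemical measurements: z1 hydrophobicity,
#' z2 steric bulk/polarizability, z3 polarity, z4/z5 electronic effects).
#'
#' @return 20 x 5 numeric matrix, rows named by one-letter residue code.
#' @export
zscales <- function() {
  m <- matrix(c(
     0.24, -2.32,  0.60, -0.14,  1.30, # A
     3.52,  2.50, -3.50,  1.99, -0.17, # R
     3.05,  1.62,  1.04, -1.15,  1.61, # N
     3.98,  0.93,  1.93, -2.46,  0.75, # D
     0.84, -1.67,  3.71,  0.18, -2.65, # C
     1.75,  0.50, -1.44, -1.34,  0.66, # Q
     3.11,  0.26, -0.11, -3.04, -0.25, # E
     2.05, -4.06,  0.36, -0.82, -0.38, # G
     2.47,  1.95,  0.26,  3.90,  0.09, # H
    -3.89, -1.73, -1.71, -0.84,  0.26, # I
    -4.28, -1.30, -1.49, -0.72,  0.84, # L
     2.29,  0.89, -2.49,  1.49,  0.31, # K
    -2.85, -0.22,  0.47,  1.94, -0.98, # M
    -4.22,  1.94,  1.06,  0.54, -0.62, # F
    -1.66,  0.27,  1.84,  0.70,  2.00, # P
     2.39, -1.07,  1.15, -1.39,  0.67, # S
     0.75, -2.18, -1.12, -1.46, -0.40, # T
    -4.36,  3.94,  0.59,  3.44, -1.59, # W
    -2.54,  2.44,  0.43,  0.04, -1.47, # Y
    -2.59, -2.64, -1.54, -0.85, -0.02  # V
  ), ncol = 5, byrow = TRUE,
  dimnames = list(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                  paste0("z", 1:5)))
  m
}

#' Extended-connectivity fingerprint of one compound
#'
#' @param smiles a single (preferably standardized) SMILES string.
#' @param radius bond radius; 3 gives ECFP-6.
#' @param n_bits fingerprint length after folding.
#' @return integer 0/1 vector of length `n_bits`.
#' @export
ecfp_fingerprint <- function(smiles, radius = 3L, n_bits = 1024L) {
  stopifnot(length(smiles) == 1L, radius %in% 1:5, is_count(n_bits))
  fp <- ob_fingerprints(smiles, type = paste0("ECFP", 2L * radius), n_bits = n_bits)
  if (anyNA(fp)) stop("invalid SMILES: ", smiles)
  fp[1L, ]
}

#' Tanimoto similarity of two fingerprints
#'
#' Intersection over union of the set bits. Two all-zero (featureless)
#' fingerprints are defined as maximally similar (1.0).
#'
#' @param a,b 0/1 vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0L) return(1.0)
  sum(a & b) / u
}

# All-pairs Tanimoto between the rows of two 0/1 matrices.
tanimoto_matrix <- function(x, y) {
  stopifnot(ncol(x) == ncol(y))
  inter <- x %*% t(y)
  rx <- rowSums(x)
  ry <- rowSums(y)
  uni <- outer(rx, ry, "+") - inter
  s <- ifelse(uni == 0, 1, inter / uni)
  s
}

#' Physicochemical property block
#'
#' Fixed-order descriptor vector per compound: molecular weight, logP
#' estimate, H-bond donors, H-bond acceptors, rotatable bonds, topological
#' polar surface area, ring count, heavy-atom count.
#'
#' @param smiles character vector of valid SMILES.
#' @return numeric matrix, one row per compound, rownames = `smiles`.
#' @export
physchem_block <- function(smiles) {
  m <- ob_physchem(smiles)
  if (anyNA(m)) {
    stop("invalid SMILES: ", paste(smiles[apply(is.na(m), 1, any)], collapse = ", "))
  }
  rownames(m) <- smiles
  m
}

#' Encode aligned sequences with a residue scale
#'
#' @param sequences named character vector of equal-length (aligned)
#'   sequences; `-` and `.` are gap characters.
#' @param scale residue-by-property numeric matrix covering the 20 standard
#'   residues (default [zscales()]).
#' @return list of per-sequence numeric matrices (alignment length x
#'   properties); gap positions are all-zero rows (the scale's neutral
#'   vector).
#' @export
residue_scale_encoding <- function(sequences, scale = zscales()) {
  stopifnot(is.character(sequences), length(sequences) > 0)
  lens <- nchar(sequences)
  assert_that(length(unique(lens)) == 1L,
              "sequences must be aligned to equal length")
  lapply(sequences, function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    gap <- chars %in% c("-", ".")
    known <- chars %in% rownames(scale) | gap
    if (!all(known)) {
      stop("unknown residue '", chars[which(!known)[1]], "' at position ",
           which(!known)[1])
    }
    m <- matrix(0, length(chars), ncol(scale),
                dimnames = list(NULL, colnames(scale)))
    m[!gap, ] <- scale[chars[!gap], , drop = FALSE]
    m
  })
}

#' Autocross-correlation transform of a per-position property matrix
#'
#' Summarizes a variable-length residue-property matrix into a fixed-length
#' vector: for every ordered property pair (j, k) and lag l in 1..max_lag,
#' the mean over positions i of the centered products x[i,j] * x[i+l,k].
#' Centering makes the transform invariant to adding a constant to any
#' property column.
#'
#' @param x numeric matrix (positions x properties).
#' @param max_lag largest positional lag; output length is
#'   `ncol(x)^2 * max_lag`.
#' @return named numeric vector.
#' @export
acc_transform <- function(x, max_lag = 3L) {
  stopifnot(is.matrix(x), is_count(max_lag), max_lag >= 1)
  if (nrow(x) <= max_lag) {
    stop("sequence length (", nrow(x), ") must exceed max_lag (", max_lag, ")")
  }
  p <- ncol(x)
  xc <- sweep(x, 2, colMeans(x))
  pn <- colnames(x)
  if (is.null(pn)) pn <- paste0("p", seq_len(p))
  out <- numeric(p * p * max_lag)
  nm <- character(length(out))
  idx <- 0L
  n <- nrow(x)
  for (l in seq_len(max_lag)) {
    a <- xc[1:(n - l), , drop = FALSE]
    b <- xc[(1 + l):n, , drop = FALSE]
    cross <- crossprod(a, b) / (n - l) # [j, k] = mean of x[i,j]*x[i+l,k]
    for (j in seq_len(p)) for (k in seq_len(p)) {
      idx <- idx + 1L
      out[idx] <- cross[j, k]
      nm[idx] <- paste0(pn[j], "_", pn[k], "_lag", l)
    }
  }
  names(out) <- nm
  out
}

#' ECFP compound descriptor block
#'
#' @param smiles character vector of standardized SMILES (duplicates allowed;
#'   computed once per unique compound).
#' @param radius bond radius (3 = ECFP-6).
#' @param n_bits fingerprint length.
#' @return 0/1 matrix, one row per unique compound, rownames = SMILES.
#' @export
compound_block_ecfp <- function(smiles, radius = 3L, n_bits = 1024L) {
  u <- unique(smiles)
  fp <- ob_fingerprints(u, type = paste0("ECFP", 2L * radius), n_bits = n_bits)
  if (anyNA(fp)) {
    stop("invalid SMILES: ", paste(u[apply(is.na(fp), 1, any)], collapse = ", "))
  }
  rownames(fp) <- u
  colnames(fp) <- paste0("ecfp", 2L * radius, "_", seq_len(n_bits))
  fp
}

#' Z-scale autocross-correlation protein block
#'
#' Encodes each sequence with a residue scale and applies [acc_transform()],
#' giving a fixed-length descriptor independent of sequence length (so no
#' alignment is required).
#'
#' @param sequences named character vector of protein sequences.
#' @param scale residue scale matrix (default [zscales()]).
#' @param max_lag autocross-correlation lag count.
#' @return numeric matrix, one row per sequence.
#' @export
protein_block_zscale_acc <- function(sequences, scale = zscales(), max_lag = 3L) {
  enc <- lapply(sequences, function(s) {
    residue_scale_encoding(stats::setNames(s, "x"), scale = scale)[[1]]
  })
  rows <- lapply(enc, acc_transform, max_lag = max_lag)
  m <- do.call(rbind, rows)
  rownames(m) <- names(sequences)
  colnames(m) <- paste0("acc_", colnames(m))
  m
}

#' Residue and dipeptide composition protein block
#'
#' Alignment-free sequence-level composition features: the 20 residue
#' frequencies followed by the 400 dipeptide frequencies.
#'
#' @param sequences named character vector of protein sequences.
#' @return numeric matrix, one row per sequence, 420 columns.
#' @export
protein_block_composition <- function(sequences) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  dip <- as.vector(outer(aa, aa, paste0))
  m <- matrix(0, length(sequences), 20 + 400,
              dimnames = list(names(sequences), c(paste0("comp_", aa), paste0("dip_", dip))))
  for (i in seq_along(sequences)) {
    chars <- strsplit(toupper(sequences[[i]]), "")[[1]]
    chars <- chars[chars %in% aa]
    tab <- table(factor(chars, levels = aa))
    m[i, 1:20] <- as.numeric(tab) / max(length(chars), 1L)
    if (length(chars) > 1L) {
      pairs <- paste0(chars[-length(chars)], chars[-1])
      dt <- table(factor(pairs, levels = dip))
      m[i, 21:420] <- as.numeric(dt) / (length(chars) - 1L)
    }
  }
  m
}

#' Assemble a PCM feature matrix from descriptor blocks
#'
#' One row per activity record; columns are the compound blocks followed by
#' the protein blocks. No cross-term columns are computed: nonlinear
#' learners capture compound-protein interplay themselves.
#'
#' @param records data.frame with columns `standardized_smiles` and
#'   `target_id`.
#' @param compound_blocks named list of matrices with SMILES rownames.
#' @param protein_blocks named list of matrices with target-id rownames
#'   (may be empty for ligand-only models).
#' @return list of class `"pcm_features"`: `x` (numeric matrix),
#'   `block_index` (named list of column index vectors), `records`.
#' @export
assemble_features <- function(records, compound_blocks, protein_blocks = list()) {
  stopifnot(is.data.frame(records),
            all(c("standardized_smiles", "target_id") %in% names(records)))
  pieces <- list()
  block_index <- list()
  at <- 0L
  add <- function(name, rows, keys) {
    miss <- setdiff(unique(keys), rownames(rows))
    if (length(miss)) {
      stop("block '", name, "' is missing entries for: ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
    m <- rows[keys, , drop = FALSE]
    colnames(m) <- paste0(name, ".", colnames(m))
    pieces[[name]] <<- m
    block_index[[name]] <<- at + seq_len(ncol(m))
    at <<- at + ncol(m)
  }
  for (nm in names(compound_blocks)) add(nm, compound_blocks[[nm]], records$standardized_smiles)
  for (nm in names(protein_blocks)) add(nm, protein_blocks[[nm]], records$target_id)
  x <- do.call(cbind, pieces)
  rownames(x) <- NULL
  structure(list(x = x, block_index = block_index, records = records),
            class = "pcm_features")
}
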