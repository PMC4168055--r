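#' Nearest-neighbor energy parameters
#'
#' Loads (and caches) the shipped thermodynamic parameter table: stacking
#' free energies (kcal/mol) for the six canonical pairs on the DNA alphabet
#' (AT/TA/GC/CG/GT/TG, i.e. AU/UA/GC/CG/GU/UG on RNA) plus linear loop
#' penalties. Hairpin loops cost `hairpin_a + hairpin_b * l` for `l >= 3`
#' unpaired bases, bulges `bulge_a + bulge_b * l`, internal loops
#' `internal_a + internal_b * (l1 + l2)` (total unpaired capped at
#' `max_internal`), and multiloops are affine:
#' `multi_a + multi_b * branches + multi_c * unpaired` (the closing pair
#' counts as a branch). GU wobble pairs are allowed; there is no
#' lonely-pair prohibition.
#'
#' @param path optional path to an alternative parameter TSV with columns
#'   `type` (stack/loop), `p1`, `p2`, `value`.
#' @return list with elements `stack` (6x6 named matrix) and `loops`
#'   (named numeric vector).
#' @export
energy_parameters <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.srnapipe_env$energy)) return(.srnapipe_env$energy)
    path <- system.file("extdata", "nn_energy_params.tsv",
                        package = "srnapipe")
    cache <- TRUE
  } else cache <- FALSE
  df <- read.delim(path, stringsAsFactors = FALSE)
  pairs <- c("AT", "TA", "GC", "CG", "GT", "TG")
  st <- df[df$type == "stack", ]
  stack <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  stack[cbind(st$p1, st$p2)] <- st$value
  if (anyNA(stack)) stop("incomplete stack table in ", path)
  lp <- df[df$type == "loop", ]
  loops <- setNames(lp$value, lp$p1)
  needed <- c("hairpin_a", "hairpin_b", "bulge_a", "bulge_b", "internal_a",
              "internal_b", "multi_a", "multi_b", "multi_c", "max_internal")
  if (!all(needed %in% names(loops)))
    stop("missing loop parameters: ",
         paste(setdiff(needed, names(loops)), collapse = ", "))
  out <- list(stack = stack, loops = loops[needed])
  if (cache) .srnapipe_env$energy <- out
  out
}

# dot-bracket -> 2-column pair matrix (1-based)
.dotbracket_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  res <- list()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") open <- c(open, i)
    else if (chars[i] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket string")
      res[[length(res) + 1L]] <- c(open[length(open)], i)
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced dot-bracket string")
  if (!length(res)) return(matrix(integer(0), ncol = 2,
                                  dimnames = list(NULL, c("i", "j"))))
  m <- do.call(rbind, res)
  colnames(m) <- c("i", "j")
  m[order(m[, 1]), , drop = FALSE]
}

#' Predict the minimum-free-energy secondary structure
#'
#' Zuker-style dynamic programming under the package's nearest-neighbor
#' model (see [energy_parameters()]). Structures are pseudoknot-free with
#' hairpin loops of at least 3 unpaired nucleotides; the empty structure
#' has energy 0, so the reported MFE is always <= 0. Among co-optimal
#' structures a fixed traceback preference order makes the result
#' deterministic.
#'
#' @param sequence DNA-alphabet string (U on input is not accepted here;
#'   normalise at ingestion).
#' @param params energy parameters from [energy_parameters()].
#' @return object of class `rna_structure`: list with `sequence`,
#'   `dotbracket`, `pairs` (2-column matrix of 1-based indices) and
#'   `energy` (kcal/mol).
#' @export
fold_mfe <- function(sequence, params = energy_parameters()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  .check_dna(sequence, "fold_mfe input")
  res <- .fold_mfe_cpp(sequence, params$stack, params$loops)
  structure(list(sequence = sequence,
                 dotbracket = res$dotbracket,
                 pairs = .dotbracket_pairs(res$dotbracket),
                 energy = res$energy),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$sequence, "\n", sep = "")
  cat(sprintf("%s (%.2f)\n", x$dotbracket, x$energy))
  invisible(x)
}

#' Evaluate the energy of a given structure
#'
#' Independent loop-decomposition evaluator for the same nearest-neighbor
#' model as [fold_mfe()]: decomposes a pair set into hairpins, stacks,
#' bulges, internal loops, multiloops and the exterior loop and sums their
#' contributions. Used for structure re-validation; shares no code with
#' the folding dynamic program.
#'
#' @param sequence DNA-alphabet string.
#' @param structure dot-bracket string or a 2-column pair matrix
#'   (1-based indices).
#' @param params energy parameters from [energy_parameters()].
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(sequence, structure,
                             params = energy_parameters()) {
  .check_dna(sequence, "structure_energy input")
  pairs <- if (is.character(structure)) {
    if (nchar(structure) != nchar(sequence))
      stop("dot-bracket length differs from sequence length")
    .dotbracket_pairs(structure)
  } else structure
  if (!nrow(pairs)) return(0)
  b <- strsplit(sequence, "")[[1]]
  pname <- paste0(b[pairs[, 1]], b[pairs[, 2]])
  ok <- pname %in% rownames(params$stack)
  if (!all(ok)) stop("non-canonical base pair: ", pname[!ok][1])
  if (any(pairs[, 2] - pairs[, 1] - 1 < 3))
    stop("hairpin loop shorter than 3 unpaired bases")
  # enclosure: for each pair, its direct parent
  o <- order(pairs[, 1])
  pairs <- pairs[o, , drop = FALSE]
  pname <- pname[o]
  np <- nrow(pairs)
  parent <- rep(0L, np)
  stack_idx <- integer(0)
  for (k in seq_len(np)) {
    while (length(stack_idx) &&
           pairs[stack_idx[length(stack_idx)], 2] < pairs[k, 1])
      stack_idx <- stack_idx[-length(stack_idx)]
    if (length(stack_idx)) {
      if (pairs[k, 2] > pairs[stack_idx[length(stack_idx)], 2])
        stop("pseudoknotted structure")
      parent[k] <- stack_idx[length(stack_idx)]
    }
    stack_idx <- c(stack_idx, k)
  }
  lp <- params$loops
  e <- 0
  for (k in seq_len(np)) {
    kids <- which(parent == k)
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!length(kids)) {
      e <- e + lp["hairpin_a"] + lp["hairpin_b"] * (j - i - 1)
    } else if (length(kids) == 1L) {
      ki <- pairs[kids, 1]; kj <- pairs[kids, 2]
      l1 <- ki - i - 1; l2 <- j - kj - 1
      if (l1 == 0 && l2 == 0) {
        e <- e + params$stack[pname[k], pname[kids]]
      } else if (l1 == 0 || l2 == 0) {
        e <- e + lp["bulge_a"] + lp["bulge_b"] * (l1 + l2)
      } else {
        e <- e + lp["internal_a"] + lp["internal_b"] * (l1 + l2)
      }
    } else {
      unpaired <- (j - i - 1) -
        sum(pairs[kids, 2] - pairs[kids, 1] + 1)
      e <- e + lp["multi_a"] + lp["multi_b"] * (length(kids) + 1) +
        lp["multi_c"] * unpaired
    }
  }
  unname(e)
}

#' Hairpin quality metrics (MFE, AMFE, MFEI, GC content)
#'
#' AMFE (adjusted MFE) is `|MFE| / length * 100`; MFEI (minimal folding
#' free energy index) is `AMFE / GC%`, the standard statistic separating
#' miRNA precursors from other RNAs.
#'
#' @param sequence precursor sequence.
#' @param mfe minimum free energy (kcal/mol); folded with [fold_mfe()]
#'   when omitted.
#' @param params energy parameters (used only when folding).
#' @return list with `mfe`, `length`, `gc_percent`, `amfe`, `mfei`
#'   (`mfei` is `NA` with a warning when GC content is 0).
#' @export
hairpin_metrics <- function(sequence, mfe = NULL,
                            params = energy_parameters()) {
  .check_dna(sequence, "hairpin_metrics input")
  if (is.null(mfe)) mfe <- fold_mfe(sequence, params)$energy
  L <- nchar(sequence)
  gc <- 100 * (L - nchar(gsub("[GC]", "", sequence))) / L
  amfe <- abs(mfe) / L * 100
  mfei <- if (gc == 0) {
    warning("GC content is 0; MFEI undefined")
    NA_real_
  } else amfe / gc
  list(mfe = mfe, length = L, gc_percent = gc, amfe = amfe, mfei = mfei)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Eulerian-walk shuffle: the output has exactly the
#' mono- and dinucleotide counts of the input and preserves the first and
#' last nucleotide. Uses the R random number generator.
#'
#' @param sequence string of length >= 3.
#' @return shuffled string.
#' @export
dinucleotide_shuffle <- function(sequence) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  if (n < 3 || length(unique(s)) == 1L) return(sequence)
  verts <- unique(s)
  last_vert <- s[n]
  # edge list per vertex
  edges <- split(s[-1], factor(s[-n], levels = verts))
  repeat {
    # choose a random final edge for every vertex except the terminal one;
    # accept when the final-edge graph connects every such vertex to the
    # terminal vertex (guarantees an Eulerian path exists in that order)
    finals <- vapply(verts, function(v) {
      if (v == last_vert || !length(edges[[v]])) NA_character_
      else sample(edges[[v]], 1)
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last_vert || !length(edges[[v]])) next
      cur <- v
      seen <- character(0)
      while (cur != last_vert) {
        if (cur %in% seen || is.na(finals[cur])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- finals[cur]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # shuffle the remaining edges, then append the final edge
  walk_edges <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (!length(e)) return(character(0))
    if (v == last_vert) return(sample(e, length(e)))
    fin <- finals[v]
    drop <- match(fin, e)
    rest <- e[-drop]
    c(if (length(rest)) sample(rest, length(rest)), fin)
  })
  names(walk_edges) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- s[1]
  cur <- s[1]
  for (k in 2:n) {
    nxt <- walk_edges[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[k] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Randomization (shuffle) test for folding significance
#'
#' Folds `n_shuffles` dinucleotide-preserving shuffles of the sequence and
#' reports the add-one Monte-Carlo p-value
#' `p = (k + 1) / (n_shuffles + 1)` where `k` counts shuffles whose MFE is
#' less than or equal to the native MFE. With 100 shuffles the attainable
#' p-values are exactly k/101 (minimum 0.009901).
#'
#' @param sequence precursor sequence.
#' @param n_shuffles number of shuffles (default 100).
#' @param seed optional integer seed for reproducibility.
#' @param params energy parameters.
#' @return list with `p_value`, `n_shuffles`, `k_not_worse`,
#'   `native_energy`.
#' @export
randomization_test <- function(sequence, n_shuffles = 100L, seed = NULL,
                               params = energy_parameters()) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  native <- fold_mfe(sequence, params)$energy
  shuffles <- vapply(seq_len(n_shuffles),
                     function(i) dinucleotide_shuffle(sequence), character(1))
  energies <- .fold_energy_cpp(shuffles, params$stack, params$loops)
  k <- sum(energies <= native + 1e-9)
  list(p_value = (k + 1) / (n_shuffles + 1),
       n_shuffles = as.integer(n_shuffles),
       k_not_worse = as.integer(k),
       native_energy = native)
}
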