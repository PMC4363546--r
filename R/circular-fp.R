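# Functional-class circular fingerprint (FCFP-style).
#
# No installed backend provides FCFP, so the Morgan iteration is implemented
# here directly: atoms start from a 6-bit functional-class invariant
# (H-bond acceptor, H-bond donor, negatively ionizable, positively ionizable,
# aromatic, halogen), and at each iteration an atom's identifier is rehashed
# from its own identifier plus the (bond-order, neighbor-identifier) multiset,
# exactly the ECFP update rule. Atom typing (aromaticity, charges) comes from
# the Open Babel MOL2 perception of the molecule, so two SMILES of the same
# molecule give the same graph and hence the same bits. Identifiers are folded
# modulo the requested length. This is a faithful member of the FCFP family,
# not a bit-for-bit clone of any particular toolkit's FCFP.

mol2_graph <- function(smiles) {
  txt <- tryCatch(ChemmineOB::convertFormat("SMILES", "MOL2", smiles),
                  error = function(e) "")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  ai <- match("@<TRIPOS>ATOM", lines)
  bi <- match("@<TRIPOS>BOND", lines)
  if (is.na(ai)) stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  sect_end <- function(start) {
    rest <- lines[seq(start + 1L, length(lines))]
    stopn <- grep("^@<TRIPOS>", rest)
    if (length(stopn)) start + stopn[[1]] - 1L else length(lines)
  }
  atom_lines <- lines[seq(ai + 1L, sect_end(ai))]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  af <- strsplit(trimws(atom_lines), "[[:space:]]+")
  type <- vapply(af, `[[`, "", 6L)
  elem <- sub("\\..*$", "", type)
  n <- length(elem)
  # formal charges live in the UNITY_ATOM_ATTR section (atom index, "charge q")
  charge <- numeric(n)
  ui <- match("@<TRIPOS>UNITY_ATOM_ATTR", lines)
  if (!is.na(ui)) {
    attr_lines <- trimws(lines[seq(ui + 1L, sect_end(ui))])
    j <- 1L
    while (j < length(attr_lines)) {
      head <- strsplit(attr_lines[[j]], "[[:space:]]+")[[1]]
      idx <- suppressWarnings(as.integer(head[[1]]))
      nattr <- suppressWarnings(as.integer(head[[2]]))
      if (is.na(idx) || is.na(nattr)) break
      for (l in seq_len(nattr)) {
        kv <- strsplit(attr_lines[[j + l]], "[[:space:]]+")[[1]]
        if (kv[[1]] == "charge") charge[[idx]] <- as.numeric(kv[[2]])
      }
      j <- j + 1L + nattr
    }
  }
  bonds <- data.frame(a = integer(), b = integer(), order = numeric())
  if (!is.na(bi)) {
    bond_lines <- lines[seq(bi + 1L, sect_end(bi))]
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
    if (length(bond_lines)) {
      bf <- strsplit(trimws(bond_lines), "[[:space:]]+")
      ord <- vapply(bf, `[[`, "", 4L)
      bonds <- data.frame(
        a = as.integer(vapply(bf, `[[`, "", 2L)),
        b = as.integer(vapply(bf, `[[`, "", 3L)),
        order = ifelse(ord == "ar", 1.5, ifelse(ord == "am", 1,
                       suppressWarnings(as.numeric(ord)))))
    }
  }
  list(elem = elem, type = type, charge = charge, bonds = bonds)
}

std_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3,
                 F = 1, Cl = 1, Br = 1, I = 1)

atom_functional_classes <- function(g) {
  n <- length(g$elem)
  bondsum <- numeric(n)
  deg <- integer(n)
  for (i in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a[[i]]; b <- g$bonds$b[[i]]; o <- g$bonds$order[[i]]
    bondsum[[a]] <- bondsum[[a]] + o; bondsum[[b]] <- bondsum[[b]] + o
    deg[[a]] <- deg[[a]] + 1L; deg[[b]] <- deg[[b]] + 1L
  }
  aromatic <- grepl("\\.ar$", g$type)
  halogen <- g$elem %in% c("F", "Cl", "Br", "I")
  val <- unname(std_valence[g$elem])
  val[is.na(val)] <- 0
  # implicit H estimate: standard valence (charge-adjusted for N+/O-) minus
  # bond order sum; aromatic ring bonds sum to 3 for a 2-connected ring atom
  val <- val + ifelse(g$elem == "N", pmax(g$charge, 0), 0) +
               ifelse(g$elem %in% c("O", "S"), pmin(g$charge, 0), 0)
  hcount <- pmax(0, round(val - bondsum))
  no <- g$elem %in% c("N", "O")
  acceptor <- no & g$charge <= 0 & !(aromatic & g$elem == "N" & hcount > 0)
  donor <- no & hcount > 0
  carboxylate <- g$type == "O.co2"
  neg <- g$charge < 0 | carboxylate
  pos <- g$charge > 0 | (g$elem == "N" & !aromatic & bondsum <= 3 &
                           hcount + deg >= 3 & hcount > 0)
  cbind(acceptor, donor, neg, pos, aromatic, halogen)
}

fp_hash <- function(ints) {
  # deterministic FNV-style hash of an integer tuple into [0, 2^31)
  h <- 2166136261
  for (x in ints) {
    h <- (bitwXor(h %% 2^31, (x + 2^20) %% 2^31) * 16777619) %% 2^31
  }
  h
}

#' Functional-class circular fingerprint
#'
#' Morgan-style circular fingerprint with functional-class initial atom
#' invariants (the FCFP scheme). See the package vignette for the exact
#' atom-typing rules used; the bits are deterministic in the molecule, not
#' in its SMILES spelling.
#'
#' @param smiles A single SMILES string.
#' @param radius Neighborhood radius (FCFP_4 uses radius 2).
#' @param nbits Folded bit-vector length.
#' @return Numeric 0/1 vector of length `nbits`.
#' @export
circular_fcfp <- function(smiles, radius = 2L, nbits = 2048L) {
  g <- mol2_graph(smiles)
  n <- length(g$elem)
  if (n == 0L) stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  classes <- atom_functional_classes(g)
  ids <- as.numeric(classes %*% 2^(0:5))  # 6-bit class code = iteration-0 id
  nbr <- vector("list", n)
  for (i in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a[[i]]; b <- g$bonds$b[[i]]
    o <- as.integer(g$bonds$order[[i]] * 2)  # 2/3/4/6 for single/ar/double/triple
    nbr[[a]] <- rbind(nbr[[a]], c(o, b))
    nbr[[b]] <- rbind(nbr[[b]], c(o, a))
  }
  all_ids <- ids
  for (r in seq_len(radius)) {
    new_ids <- numeric(n)
    for (i in seq_len(n)) {
      env <- nbr[[i]]
      if (is.null(env)) {
        new_ids[[i]] <- fp_hash(c(r, ids[[i]]))
        next
      }
      pairs <- cbind(env[, 1L], ids[env[, 2L]])
      ord <- order(pairs[, 2L], pairs[, 1L])
      new_ids[[i]] <- fp_hash(c(r, ids[[i]], t(pairs[ord, , drop = FALSE])))
    }
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  v <- numeric(nbits)
  v[(all_ids %% nbits) + 1L] <- 1
  v
}
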