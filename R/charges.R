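## Gasteiger-Marsili partial charges (PEOE: partial equalization of orbital
## electronegativity). Electronegativity of atom i at charge q is the
## quadratic chi(q) = a + b q + c q^2; at each iteration k charge
## (chi_j - chi_i) / chi_plus_donor * (1/2)^k flows across every bond from
## the less to the more electronegative end, with chi_plus the cation
## electronegativity (a + b + c; 20.02 for hydrogen). Six iterations with
## the damping factor halving each round, as in the original scheme.

.PEOE <- rbind(
  H    = c(7.17, 6.24, -0.56),
  Csp3 = c(7.98, 9.18, 1.88),
  Csp2 = c(8.79, 9.32, 1.51),
  Csp1 = c(10.39, 9.45, 0.73),
  Nsp3 = c(11.54, 10.82, 1.36),
  Nsp2 = c(12.87, 11.15, 0.85),
  Nsp1 = c(15.68, 11.70, -0.27),
  Osp3 = c(14.18, 12.92, 1.39),
  Osp2 = c(17.07, 13.79, 0.47),
  F    = c(14.66, 13.85, 2.31),
  Cl   = c(11.00, 9.69, 1.35),
  Br   = c(10.08, 8.47, 1.16),
  I    = c(9.90, 7.96, 0.96),
  S    = c(10.14, 9.13, 1.38))

.peoeType <- function(atoms, bonds, i) {
  el <- atoms$element[i]
  if (el %in% c("H", "F", "Cl", "Br", "I", "S")) return(el)
  if (!el %in% c("C", "N", "O")) return("Csp3")  # fallback for rare elements
  k <- which(bonds$a1 == i | bonds$a2 == i)
  orders <- bonds$order[k]
  hyb <- if (el == "O") {
    if (any(orders == 2L) || atoms$aromatic[i]) "sp2" else "sp3"
  } else if (any(orders == 3L) || sum(orders == 2L) >= 2L) {
    "sp1"
  } else if (any(orders == 2L) || atoms$aromatic[i]) {
    "sp2"
  } else "sp3"
  paste0(el, hyb)
}

#' Gasteiger-Marsili partial charges
#'
#' Iterative partial equalization of orbital electronegativity over the
#' molecular graph, with implicit hydrogens included as pseudo-atoms.
#'
#' @param cpd a \linkS4class{Compound} with a parsed molecular graph.
#' @param foldHydrogens fold every hydrogen charge into its bonded heavy
#'   atom (united-atom charges); hydrogens carry no coordinates when
#'   implicit, so folded charges are what the field code consumes.
#' @param nIter number of damping iterations (default 6).
#' @return numeric vector of partial charges, one per heavy atom in graph
#'   order (or one per atom including explicit H when
#'   \code{foldHydrogens = FALSE}).
#' @examples
#' q <- gasteigerCharges(compound("etoh", "CCO"))
#' q  # oxygen carries the negative charge
#' @export
gasteigerCharges <- function(cpd, foldHydrogens = TRUE, nIter = 6L) {
  stopifnot(is(cpd, "Compound"))
  if (is.null(cpd@graph)) stop("compound '", cpd@id, "' has no graph")
  atoms <- cpd@graph$atoms
  bonds <- cpd@graph$bonds
  n0 <- nrow(atoms)
  ## append implicit hydrogens as explicit pseudo-atoms
  el <- atoms$element
  heavyParent <- integer(0)
  for (i in seq_len(n0)) {
    nImp <- atoms$nH[i] - sum(el[c(bonds$a2[bonds$a1 == i],
                                   bonds$a1[bonds$a2 == i])] == "H")
    if (nImp > 0L) heavyParent <- c(heavyParent, rep(i, nImp))
  }
  nH <- length(heavyParent)
  n <- n0 + nH
  element <- c(el, rep("H", nH))
  aromatic <- c(atoms$aromatic, rep(FALSE, nH))
  allBonds <- rbind(bonds[, c("a1", "a2", "order")],
                    data.frame(a1 = heavyParent,
                               a2 = n0 + seq_len(nH),
                               order = rep(1L, max(nH, 0L))))
  atomsX <- data.frame(element = element, aromatic = aromatic)
  type <- vapply(seq_len(n), function(i) .peoeType(atomsX, allBonds, i),
                 character(1))
  par <- .PEOE[type, , drop = FALSE]
  chiPlus <- rowSums(par)
  chiPlus[element == "H"] <- 20.02
  q <- c(as.numeric(atoms$charge), rep(0, nH))
  damp <- 1
  for (it in seq_len(nIter)) {
    damp <- damp / 2
    chi <- par[, 1] + par[, 2] * q + par[, 3] * q^2
    dq <- numeric(n)
    for (k in seq_len(nrow(allBonds))) {
      i <- allBonds$a1[k]; j <- allBonds$a2[k]
      if (chi[i] < chi[j]) {
        d <- (chi[j] - chi[i]) / chiPlus[i] * damp
        dq[i] <- dq[i] + d; dq[j] <- dq[j] - d
      } else if (chi[j] < chi[i]) {
        d <- (chi[i] - chi[j]) / chiPlus[j] * damp
        dq[j] <- dq[j] + d; dq[i] <- dq[i] - d
      }
    }
    q <- q + dq
  }
  if (foldHydrogens) {
    for (k in seq_len(nrow(allBonds))) {
      i <- allBonds$a1[k]; j <- allBonds$a2[k]
      if (element[j] == "H" && element[i] != "H") {
        q[i] <- q[i] + q[j]; q[j] <- 0
      } else if (element[i] == "H" && element[j] != "H") {
        q[j] <- q[j] + q[i]; q[i] <- 0
      }
    }
    q <- q[seq_len(n0)][!atoms$isH]
  } else {
    q <- q[seq_len(n0)]
  }
  unname(q)
}
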