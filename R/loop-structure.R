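#' Canonical vestibulocerebellar loop structure
#'
#' Builds the signed 4x4 connection pattern of the bilateral
#' vestibulocerebellar circuit: two Purkinje-cell populations (`PJ_A`,
#' `PJ_B`, one per brainstem side) and two vestibular-nuclei populations
#' (`VN_A`, `VN_B`). The digraph contains two ipsilateral negative loops
#' (one inhibitory edge each, on node pairs \{1,2\} and \{3,4\}), a central
#' commissural double-negative loop (two inhibitory edges, nodes \{2,3\}),
#' and two additional contralateral inhibitory edges (3 to 1 and 2 to 4).
#' Every node also carries a self-inhibitory (leak) term on the diagonal.
#'
#' @return An object of class `loop_structure`: a list with `node_labels`
#'   (character, length 4), `sign_pattern` (4x4 matrix in \{-1, 0, 1\}) and
#'   `entry_class` (4x4 character matrix: `"self"`, `"excitatory"`,
#'   `"inhibitory"` or `"absent"`).
#' @examples
#' st <- canonical_structure()
#' st$sign_pattern
#' @seealso [weight_scheme()], [sample_jacobian()]
#' @export
canonical_structure <- function() {
  labels <- c("PJ_A", "VN_A", "VN_B", "PJ_B")
  sign_pattern <- matrix(c(
    -1,  1, -1,  0,
    -1, -1, -1,  0,
     0, -1, -1, -1,
     0, -1,  1, -1), nrow = 4, byrow = TRUE,
    dimnames = list(labels, labels))
  entry_class <- matrix("absent", 4, 4, dimnames = dimnames(sign_pattern))
  diag(entry_class) <- "self"
  entry_class[cbind(c(1, 4), c(2, 3))] <- "excitatory"
  entry_class[cbind(c(1, 2, 2, 3, 3, 4), c(3, 1, 3, 2, 4, 2))] <- "inhibitory"
  structure(list(node_labels = labels,
                 sign_pattern = sign_pattern,
                 entry_class = entry_class),
            class = "loop_structure")
}

#' @export
print.loop_structure <- function(x, ...) {
  cat("Vestibulocerebellar loop structure (", paste(x$node_labels,
      collapse = ", "), ")\n", sep = "")
  cat("Sign pattern:\n")
  print(x$sign_pattern)
  invisible(x)
}

#' Connection-class weight scheme
#'
#' Scaling coefficients applied to the three connection classes of a
#' [loop structure][canonical_structure]: self-inhibitory (diagonal; the
#' quantity usually written d), excitatory, and inhibitory. All weights are
#' in arbitrary units.
#'
#' @param w_self Positive scale of the diagonal self-inhibitory entries.
#' @param w_exc Scale of the two excitatory entries.
#' @param w_inh Scale of the six inhibitory off-diagonal entries.
#' @return An object of class `weight_scheme`.
#' @examples
#' weight_scheme(w_self = 1, w_exc = 10, w_inh = 30)
#' @export
weight_scheme <- function(w_self = 1, w_exc = 1, w_inh = 1) {
  for (nm in c("w_self", "w_exc", "w_inh")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("'%s' must be a single finite non-negative number", nm),
           call. = FALSE)
  }
  structure(list(w_self = w_self, w_exc = w_exc, w_inh = w_inh),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat(sprintf("Weight scheme: self %g, excitatory %g, inhibitory %g (a.u.)\n",
              x$w_self, x$w_exc, x$w_inh))
  invisible(x)
}

# 4x4 matrix of per-entry class weights for a structure/scheme pair
class_weights <- function(structure, scheme) {
  w <- matrix(0, 4, 4, dimnames = dimnames(structure$sign_pattern))
  w[structure$entry_class == "self"] <- scheme$w_self
  w[structure$entry_class == "excitatory"] <- scheme$w_exc
  w[structure$entry_class == "inhibitory"] <- scheme$w_inh
  w
}

as_weight_scheme <- function(x) {
  if (inherits(x, "weight_scheme")) return(x)
  if (is.numeric(x) && length(x) == 3L)
    return(weight_scheme(w_self = x[[1]], w_exc = x[[2]], w_inh = x[[3]]))
  stop("expected a 'weight_scheme' or a numeric vector (w_self, w_exc, w_inh)",
       call. = FALSE)
}
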