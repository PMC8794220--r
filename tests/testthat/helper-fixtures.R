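# Shared fixture builders: tiny residues, chains and structure files built
# in code at test time.

make_residue <- function(xyz, name, element = NULL, aa = "ALA") {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3L, byrow = TRUE)
  if (is.null(element))
    element <- ifelse(grepl("^H", name), "H", substr(name, 1L, 1L))
  list(xyz = xyz, name = name, element = element, aa = aa)
}

# residue with the canonical 5-atom example: N, CA, C, O heavy + HA hydrogen
residue_5atom <- function(origin = c(0, 0, 0)) {
  make_residue(rbind(origin,
                     origin + c(1.5, 0, 0),
                     origin + c(2.5, 1, 0),
                     origin + c(3.5, 1, 1),
                     origin + c(1.5, 1, 0)),
               name = c("N", "CA", "C", "O", "HA"),
               element = c("N", "C", "C", "O", "H"))
}

random_residue <- function(n_atoms = 5L, center = c(0, 0, 0), with_h = TRUE) {
  xyz <- sweep(matrix(rnorm(3L * n_atoms), ncol = 3L), 2L, center, "+")
  elem <- c("C", sample(c("C", "N", "O", if (with_h) "H"), n_atoms - 1L,
                        replace = TRUE))
  make_residue(xyz, name = paste0(elem, seq_len(n_atoms)), element = elem)
}

# a chain with full atom records: CA trace plus per-residue extra atoms
atomful_chain <- function(N = 6L, seed = 42L, with_h = TRUE) {
  set.seed(seed)
  ca <- 4 * matrix(cumsum(rnorm(3L * N)), ncol = 3L)
  atoms <- lapply(seq_len(N), function(i) {
    r <- random_residue(4L, center = ca[i, ], with_h = with_h)
    r$xyz <- rbind(ca[i, ], r$xyz)
    r$name <- c("CA", r$name)
    r$element <- c("C", r$element)
    r
  })
  new_chain(ca, aa = sample(c("ALA", "GLY", "CYS"), N, replace = TRUE),
            atoms = atoms)
}

maxwell_cdf <- function(R, b, m) pchisq(3 * R^2 / (b^2 * m), df = 3)

# direct (independent-path) log-likelihood maximizer for the Maxwell scale
numeric_kuhn_mle <- function(x, m, interval_mult = c(0.2, 5)) {
  b0 <- sqrt(mean(x^2) / m)
  negll <- function(b) -sum(log(maxwell_pdf(x, b, m)))
  optimize(negll, interval = interval_mult * b0, tol = 1e-10)$minimum
}
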