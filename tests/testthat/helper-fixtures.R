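# Shared fixtures and independent numerical oracles for the test suite.

oxy <- oxybenzone_properties()
forms <- formulation_fixtures()
truths <- dermal_truth_params()
stack_vitro <- skin_stack_invitro()
stack_vivo <- skin_stack_invivo()

# Brute-force finite-difference oracle for 1-D membrane diffusion with a
# constant donor (membrane surface held at K * c_d) and a perfect sink at
# the base. Independent of the package's finite-volume engine: 400 interior
# nodes, second-order central Laplacian, exact time integration of the
# resulting linear system u' = A u + b through the eigendecomposition of A,
# and cumulative basal flux from the exact time integral of u with a
# second-order one-sided flux stencil. Units: d [cm^2/h], l [cm], t [h].
fd_membrane_oracle <- function(d, k, l_cm, c_d, times, nx = 400) {
  h <- l_cm / (nx + 1)              # interior nodes at i*h, i = 1..nx
  a <- d / h^2
  A <- diag(rep(-2 * a, nx))
  A[cbind(1:(nx - 1), 2:nx)] <- a
  A[cbind(2:nx, 1:(nx - 1))] <- a
  b <- c(a * k * c_d, rep(0, nx - 1))
  e <- eigen(A, symmetric = TRUE)
  w <- crossprod(e$vectors, b)
  f <- numeric(nx)                  # flux into sink: D (4 u_n - u_{n-1})/(2h)
  f[nx] <- 4 * d / (2 * h); f[nx - 1] <- -d / (2 * h)
  fv <- crossprod(e$vectors, f)
  lam <- e$values
  q <- vapply(times, function(t) {
    g <- (exp(lam * t) - 1) / lam^2 - t / lam   # int_0^t of the modal ODE
    sum(fv * g * w)
  }, numeric(1))
  data.frame(time_h = times, q_ug_cm2 = q)
}

# Small memo cache so expensive synthetic datasets are built once per file.
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# Noise-only (no donor thickness jitter) four-formulation synthetic study,
# used by the refinement closure tests.
closure_datasets <- function(noise_cv = 0.05, n_replicates = 8, seed = 101) {
  key <- paste0("closure_", noise_cv, "_", n_replicates, "_", seed)
  cached(key, {
    fix <- lapply(names(forms), function(nm)
      gen_franz_dataset(oxy, forms[[nm]], truths[[nm]], noise_cv = noise_cv,
                        n_replicates = n_replicates, seed = seed,
                        thickness_sd = 0))
    names(fix) <- names(forms)
    lapply(fix, `[[`, "dataset")
  })
}

stage1_truth <- c(d_ve = 5e-8, k_ve_w = 8, k_de_w = 3)
stage1_bounds <- list(start = c(d_ve = 2e-8, k_ve_w = 4, k_de_w = 2),
                      lower = c(d_ve = 1e-9, k_ve_w = 0.5, k_de_w = 0.3),
                      upper = c(d_ve = 1e-6, k_ve_w = 50, k_de_w = 30))
stage2_truth_f1 <- c(k_vh_w = 2000, d_sc = 8e-10, k_sc_w = 220,
                     application_time = 0.475)
stage2_bounds <- list(
  start = c(k_vh_w = 800, d_sc = 2e-9, k_sc_w = 100, application_time = 0.5),
  lower = c(k_vh_w = 100, d_sc = 5e-11, k_sc_w = 10, application_time = 0.1),
  upper = c(k_vh_w = 10000, d_sc = 5e-8, k_sc_w = 1000, application_time = 6))
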