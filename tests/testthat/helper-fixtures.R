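# Shared fixtures: a default component library and a builder for
# three-component SORS-like mixtures with known ground truth.

fixture_lib <- make_component_library()

# mixtures of one bone spectrum with a lipid+skin overlayer at varying
# soft-tissue weight; returns the set plus the true bone vector
make_mixture_set <- function(n = 10, noise_sd = 0.02, seed = 1,
                             w_range = c(0.3, 0.8), ratio = NULL,
                             lib = fixture_lib) {
  set.seed(seed)
  if (is.null(ratio)) ratio <- runif(1, 0.8, 1.2)
  bone <- generate_bone_spectrum(lib, ratio)
  soft <- lib$components[, "lipid"] + lib$components[, "skin_matrix"]
  w <- runif(n, w_range[1], w_range[2])
  mat <- t(sapply(w, function(wi) {
    (1 - wi) * bone$intensity + wi * soft +
      rnorm(length(bone$intensity), sd = noise_sd)
  }))
  list(set = spectrum_set(lib$wavenumber, mat),
       bone = bone$intensity, soft = soft, w = w, ratio = ratio)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
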