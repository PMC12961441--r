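# Layer constructors on top of the autodiff engine. A "module" is a plain
# list of parameter nodes plus metadata; nn_params() collects the parameters
# recursively for the optimizer.

nn_linear <- function(d_in, d_out, bias = TRUE, zero_init = FALSE) {
  W <- if (zero_init) matrix(0, d_in, d_out)
       else matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out)
  lin <- list(W = ag_param(W), d_in = d_in, d_out = d_out)
  if (bias) lin$b <- ag_param(matrix(0, 1L, d_out), no_decay = TRUE)
  lin
}

nn_linear_forward <- function(lin, x) {
  y <- ag_mm(x, lin$W)
  if (!is.null(lin$b)) y <- ag_add(y, lin$b)
  y
}

nn_bn <- function(d) {
  list(gamma = ag_param(matrix(1, 1L, d), no_decay = TRUE),
       beta = ag_param(matrix(0, 1L, d), no_decay = TRUE))
}

nn_bn_forward <- function(bn, x) ag_pointbn(x, bn$gamma, bn$beta)

# phi = ReLU(PointBN(Linear(x)))
nn_lbr <- function(d_in, d_out) {
  list(lin = nn_linear(d_in, d_out), bn = nn_bn(d_out))
}

nn_lbr_forward <- function(m, x) ag_relu(nn_bn_forward(m$bn, nn_linear_forward(m$lin, x)))

# small MLP: hidden layers with ReLU, plain linear output (optionally
# zero-initialized so the block starts silent)
nn_mlp <- function(dims, zero_last = FALSE) {
  L <- length(dims) - 1L
  layers <- vector("list", L)
  for (i in seq_len(L))
    layers[[i]] <- nn_linear(dims[i], dims[i + 1L],
                             zero_init = zero_last && i == L)
  list(layers = layers, n = L)
}

nn_mlp_forward <- function(m, x) {
  for (i in seq_len(m$n)) {
    x <- nn_linear_forward(m$layers[[i]], x)
    if (i < m$n) x <- ag_relu(x)
  }
  x
}
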