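#include <Rcpp.h>
using namespace Rcpp;

// Per-sample (stochastic) gradient descent for an M -> H -> 1 network with
// logistic activations everywhere, trained against {0,1} targets, with
// early stopping on test-subset accuracy. The shuffle uses R's RNG via a
// Fisher-Yates pass so runs are reproducible from set.seed() and can be
// replayed exactly by the pure-R reference implementation used in tests.

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static void fisher_yates(std::vector<int>& perm) {
  const int n = perm.size();
  for (int i = n - 1; i >= 1; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;  // guard the unif_rand()==1.0 edge
    std::swap(perm[i], perm[j]);
  }
}

// [[Rcpp::export]]
List cpp_train_ann(NumericMatrix Xtr, NumericVector ttr,
                   NumericMatrix Xte, IntegerVector yte,
                   NumericMatrix W1_, NumericVector b1_,
                   NumericVector W2_, double b2_,
                   double lr, int max_epochs, int patience,
                   int loss_type, double threshold) {
  const int n = Xtr.nrow(), m = Xtr.ncol(), h = W1_.nrow();
  const int nte = Xte.nrow();

  std::vector<double> W1(W1_.begin(), W1_.end());   // h x m, column-major
  std::vector<double> b1(b1_.begin(), b1_.end());
  std::vector<double> W2(W2_.begin(), W2_.end());
  double b2 = b2_;

  std::vector<double> bestW1(W1), bestb1(b1), bestW2(W2);
  double bestb2 = b2, best_acc = -1.0;
  int best_epoch = 0, since_best = 0;

  std::vector<double> hidden(h), train_loss, test_acc;
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  std::string stopped = "max_epochs";
  int bad_epoch = -1;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    fisher_yates(perm);
    double loss_sum = 0.0;
    for (int s = 0; s < n; ++s) {
      const int i = perm[s];
      // forward
      double z2 = b2;
      for (int k = 0; k < h; ++k) {
        double z1 = b1[k];
        for (int j = 0; j < m; ++j) z1 += W1[k + h * j] * Xtr(i, j);
        hidden[k] = sigmoid(z1);
        z2 += W2[k] * hidden[k];
      }
      const double o = sigmoid(z2);
      const double t = ttr[i];
      double loss, delta2;
      if (loss_type == 0) {            // mean squared error on {0,1} targets
        loss = (o - t) * (o - t);
        delta2 = 2.0 * (o - t) * o * (1.0 - o);
      } else {                         // log-loss
        const double eps = 1e-12;
        loss = -t * std::log(o + eps) - (1.0 - t) * std::log(1.0 - o + eps);
        delta2 = o - t;
      }
      loss_sum += loss;
      // backprop + update
      for (int k = 0; k < h; ++k) {
        const double delta1 = delta2 * W2[k] * hidden[k] * (1.0 - hidden[k]);
        W2[k] -= lr * delta2 * hidden[k];
        for (int j = 0; j < m; ++j) W1[k + h * j] -= lr * delta1 * Xtr(i, j);
        b1[k] -= lr * delta1;
      }
      b2 -= lr * delta2;
    }
    const double mean_loss = loss_sum / n;
    if (!std::isfinite(mean_loss)) { bad_epoch = epoch; break; }

    // test-subset accuracy with the current weights
    int correct = 0;
    for (int i = 0; i < nte; ++i) {
      double z2 = b2;
      for (int k = 0; k < h; ++k) {
        double z1 = b1[k];
        for (int j = 0; j < m; ++j) z1 += W1[k + h * j] * Xte(i, j);
        z2 += W2[k] * sigmoid(z1);
      }
      const int call = (sigmoid(z2) >= threshold) ? 1 : -1;
      if (call == yte[i]) ++correct;
    }
    const double acc = (double)correct / nte;
    train_loss.push_back(mean_loss);
    test_acc.push_back(acc);

    if (acc > best_acc) {              // ties keep the earlier epoch
      best_acc = acc;
      best_epoch = epoch;
      bestW1 = W1; bestb1 = b1; bestW2 = W2; bestb2 = b2;
      since_best = 0;
    } else if (++since_best >= patience) {
      stopped = "patience";
      break;
    }
  }

  NumericMatrix outW1(h, m);
  std::copy(bestW1.begin(), bestW1.end(), outW1.begin());
  NumericMatrix hist(train_loss.size(), 2);
  for (size_t e = 0; e < train_loss.size(); ++e) {
    hist(e, 0) = train_loss[e];
    hist(e, 1) = test_acc[e];
  }
  return List::create(
    _["W1"] = outW1, _["b1"] = NumericVector(bestb1.begin(), bestb1.end()),
    _["W2"] = NumericVector(bestW2.begin(), bestW2.end()), _["b2"] = bestb2,
    _["history"] = hist, _["best_epoch"] = best_epoch,
    _["best_acc"] = best_acc, _["stopped"] = stopped,
    _["bad_epoch"] = bad_epoch);
}
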