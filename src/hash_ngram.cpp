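#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

static const uint64_t FNV_OFFSET = 1469598103934665603ULL * 10ULL + 7ULL; // 14695981039346656037
static const uint64_t FNV_PRIME  = 1099511628211ULL;

static inline uint64_t fnv1a64(const char *s, size_t n) {
  uint64_t h = FNV_OFFSET;
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= FNV_PRIME;
  }
  return h;
}

// FNV-1a (64-bit) of each string's UTF-8 bytes, reduced modulo `dim`.
// [[Rcpp::export]]
IntegerVector cpp_fnv1a_mod(CharacterVector x, double dim) {
  if (dim < 1) stop("`dim` must be >= 1");
  uint64_t m = (uint64_t)dim;
  int n = x.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(x, i));
    out[i] = (int)(fnv1a64(s, strlen(s)) % m);
  }
  return out;
}

// Character 3-gram bucket counts for each text. Texts must already be
// NFC-normalised and lowercased; each is padded with '^' and '$' here.
// Grams span Unicode code points (UTF-8 boundaries), hashing the raw bytes.
// [[Rcpp::export]]
NumericMatrix cpp_hash_ngram_counts(CharacterVector texts, int dim) {
  if (dim < 2) stop("`dim` must be >= 2");
  int n = texts.size();
  NumericMatrix counts(n, dim);
  for (int i = 0; i < n; ++i) {
    std::string padded = "^";
    padded += CHAR(STRING_ELT(texts, i));
    padded += "$";
    // code-point start offsets (continuation bytes have 10xxxxxx prefix)
    std::vector<size_t> starts;
    for (size_t b = 0; b < padded.size(); ++b)
      if (((unsigned char)padded[b] & 0xC0) != 0x80) starts.push_back(b);
    starts.push_back(padded.size());
    size_t nchar_i = starts.size() - 1;
    if (nchar_i < 3) continue; // text shorter than 1 char is rejected upstream
    for (size_t c = 0; c + 3 <= nchar_i; ++c) {
      size_t from = starts[c], to = starts[c + 3];
      uint64_t h = fnv1a64(padded.data() + from, to - from);
      counts(i, (int)(h % (uint64_t)dim)) += 1.0;
    }
  }
  return counts;
}
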