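// Minimal SHA-1 (FIPS 180-1) used for the keyed kmer hash h_K(s): the first
// 64 bits of SHA-1(K || s) with a 256-bit secret key K. Message sizes here
// are tiny (40 bytes), so a straightforward block implementation suffices.
#include "mv_core.h"

static inline uint32_t rotl32(uint32_t x, int n) {
  return (x << n) | (x >> (32 - n));
}

void sha1_digest(const uint8_t* data, size_t len, uint8_t out[20]) {
  uint32_t h0 = 0x67452301u, h1 = 0xEFCDAB89u, h2 = 0x98BADCFEu,
           h3 = 0x10325476u, h4 = 0xC3D2E1F0u;

  // padded message: len + 1 + zeros + 8, multiple of 64
  size_t total = ((len + 8) / 64 + 1) * 64;
  std::vector<uint8_t> msg(total, 0);
  std::copy(data, data + len, msg.begin());
  msg[len] = 0x80;
  uint64_t bits = (uint64_t)len * 8;
  for (int i = 0; i < 8; ++i)
    msg[total - 1 - i] = (uint8_t)(bits >> (8 * i));

  uint32_t w[80];
  for (size_t off = 0; off < total; off += 64) {
    const uint8_t* p = msg.data() + off;
    for (int i = 0; i < 16; ++i)
      w[i] = ((uint32_t)p[4 * i] << 24) | ((uint32_t)p[4 * i + 1] << 16) |
             ((uint32_t)p[4 * i + 2] << 8) | (uint32_t)p[4 * i + 3];
    for (int i = 16; i < 80; ++i)
      w[i] = rotl32(w[i - 3] ^ w[i - 8] ^ w[i - 14] ^ w[i - 16], 1);

    uint32_t a = h0, b = h1, c = h2, d = h3, e = h4;
    for (int i = 0; i < 80; ++i) {
      uint32_t f, k;
      if (i < 20)      { f = (b & c) | ((~b) & d);          k = 0x5A827999u; }
      else if (i < 40) { f = b ^ c ^ d;                     k = 0x6ED9EBA1u; }
      else if (i < 60) { f = (b & c) | (b & d) | (c & d);   k = 0x8F1BBCDCu; }
      else             { f = b ^ c ^ d;                     k = 0xCA62C1D6u; }
      uint32_t tmp = rotl32(a, 5) + f + e + k + w[i];
      e = d; d = c; c = rotl32(b, 30); b = a; a = tmp;
    }
    h0 += a; h1 += b; h2 += c; h3 += d; h4 += e;
  }

  uint32_t hs[5] = {h0, h1, h2, h3, h4};
  for (int i = 0; i < 5; ++i) {
    out[4 * i] = (uint8_t)(hs[i] >> 24);
    out[4 * i + 1] = (uint8_t)(hs[i] >> 16);
    out[4 * i + 2] = (uint8_t)(hs[i] >> 8);
    out[4 * i + 3] = (uint8_t)hs[i];
  }
}

uint64_t keyed_base_hash(const uint8_t K[32], uint64_t code) {
  uint8_t buf[40];
  std::copy(K, K + 32, buf);
  for (int i = 0; i < 8; ++i) buf[32 + i] = (uint8_t)(code >> (8 * (7 - i)));
  uint8_t dig[20];
  sha1_digest(buf, 40, dig);
  uint64_t h = 0;
  for (int i = 0; i < 8; ++i) h = (h << 8) | dig[i];
  return h;
}
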