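// Raster helpers: CRC32 for the PNG codec, PNG scanline (un)filtering,
// procedural disc painting for the synthetic-texture generator, and
// block-average downsampling for the CNN backbone input.

#include <Rcpp.h>
#include <cstdint>

using namespace Rcpp;

// [[Rcpp::export(name = ".crc32")]]
double crc32_raw(RawVector data, double init) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k) c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    have_table = true;
  }
  uint32_t crc = (uint32_t)init ^ 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}

// Undo PNG per-scanline filters (types 0-4) in place over the decompressed
// stream: height rows of (1 filter byte + width*channels bytes).
// Returns the defiltered pixel bytes, row-major, interleaved channels.
// [[Rcpp::export(name = ".png_unfilter")]]
RawVector png_unfilter(RawVector data, int width, int height, int channels) {
  int stride = width * channels;
  if ((R_xlen_t)(stride + 1) * height != data.size())
    stop("decompressed PNG stream has unexpected length");
  RawVector out((R_xlen_t)stride * height);
  std::vector<uint8_t> prev(stride, 0), cur(stride);
  for (int r = 0; r < height; ++r) {
    const uint8_t* src = (const uint8_t*)RAW(data) + (R_xlen_t)r * (stride + 1);
    int ft = src[0];
    ++src;
    for (int i = 0; i < stride; ++i) {
      int a = i >= channels ? cur[i - channels] : 0;  // left
      int b = prev[i];                                // up
      int c = i >= channels ? prev[i - channels] : 0; // upper-left
      int x = src[i];
      int v;
      switch (ft) {
        case 0: v = x; break;
        case 1: v = x + a; break;
        case 2: v = x + b; break;
        case 3: v = x + (a + b) / 2; break;
        case 4: {
          int p = a + b - c;
          int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
          int pr = (pa <= pb && pa <= pc) ? a : (pb <= pc ? b : c);
          v = x + pr;
          break;
        }
        default: stop("unsupported PNG filter type %d", ft);
      }
      cur[i] = (uint8_t)(v & 0xFF);
    }
    std::copy(cur.begin(), cur.end(), (uint8_t*)RAW(out) + (R_xlen_t)r * stride);
    prev.swap(cur);
  }
  return out;
}

// Apply filter type 0 (none) to every scanline: prepend a zero byte per row.
// [[Rcpp::export(name = ".png_filter0")]]
RawVector png_filter0(RawVector pixels, int width, int height, int channels) {
  int stride = width * channels;
  if ((R_xlen_t)stride * height != pixels.size()) stop("pixel buffer length mismatch");
  RawVector out((R_xlen_t)(stride + 1) * height);
  for (int r = 0; r < height; ++r) {
    uint8_t* dst = (uint8_t*)RAW(out) + (R_xlen_t)r * (stride + 1);
    dst[0] = 0;
    std::copy((const uint8_t*)RAW(pixels) + (R_xlen_t)r * stride,
              (const uint8_t*)RAW(pixels) + (R_xlen_t)(r + 1) * stride, dst + 1);
  }
  return out;
}

// Paint filled discs onto an H x W x 3 integer image (R array, modified copy).
// cx, cy are 1-based centre coordinates; col is n x 3 (0-255).
// [[Rcpp::export(name = ".paint_discs")]]
IntegerVector paint_discs(IntegerVector img, int height, int width,
                          IntegerVector cx, IntegerVector cy,
                          IntegerVector radius, IntegerMatrix col) {
  IntegerVector out = clone(img);
  int n = cx.size();
  for (int k = 0; k < n; ++k) {
    int x = cx[k] - 1, y = cy[k] - 1, r = radius[k];
    int r2 = r * r;
    for (int dj = -r; dj <= r; ++dj) {
      int j = x + dj;
      if (j < 0 || j >= width) continue;
      for (int di = -r; di <= r; ++di) {
        int i = y + di;
        if (i < 0 || i >= height) continue;
        if (di * di + dj * dj > r2) continue;
        for (int c = 0; c < 3; ++c)
          out[i + (R_xlen_t)height * j + (R_xlen_t)height * width * c] = col(k, c);
      }
    }
  }
  return out;
}

// Block-average downsample of an H x W x C numeric array by integer factor f.
// [[Rcpp::export(name = ".block_mean")]]
NumericVector block_mean(NumericVector img, int height, int width, int channels,
                         int factor) {
  if (height % factor != 0 || width % factor != 0)
    stop("image side not divisible by pooling factor");
  int h = height / factor, w = width / factor;
  NumericVector out((R_xlen_t)h * w * channels);
  double inv = 1.0 / (factor * factor);
  for (int c = 0; c < channels; ++c) {
    R_xlen_t oin = (R_xlen_t)height * width * c;
    R_xlen_t oout = (R_xlen_t)h * w * c;
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        double s = 0;
        for (int dj = 0; dj < factor; ++dj)
          for (int di = 0; di < factor; ++di)
            s += img[oin + (i * factor + di) + (R_xlen_t)height * (j * factor + dj)];
        out[oout + i + (R_xlen_t)h * j] = s * inv;
      }
    }
  }
  return out;
}
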