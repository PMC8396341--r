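// Minimal PNG codec for the two pixel formats the package emits:
// 8-bit RGB tiles and 16-bit grayscale density-map previews.
// Compression is delegated to the system zlib; scanline filters 0-4 are
// handled on read, filter 0 is used on write.
#include <Rcpp.h>
#include <zlib.h>
#include <cstring>

using namespace Rcpp;

static void push_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

static void push_chunk(std::vector<unsigned char>& out, const char type[4],
                       const unsigned char* data, size_t n) {
  push_u32(out, (uint32_t)n);
  size_t start = out.size();
  out.insert(out.end(), type, type + 4);
  if (n) out.insert(out.end(), data, data + n);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, out.data() + start, (uInt)(n + 4));
  push_u32(out, (uint32_t)crc);
}

// [[Rcpp::export(name = ".png_encode")]]
RawVector png_encode(IntegerVector pixels, int height, int width,
                     int channels, int bitdepth) {
  // pixels: row-major scanline order (y, then x, then channel), host ints
  if (!((channels == 3 && bitdepth == 8) || (channels == 1 && bitdepth == 16)))
    stop("unsupported PNG format: %d channels at bit depth %d", channels, bitdepth);
  const int bpp = channels * bitdepth / 8;
  const size_t stride = (size_t)width * bpp;
  std::vector<unsigned char> raw((stride + 1) * height);
  size_t k = 0;
  for (int y = 0; y < height; ++y) {
    raw[y * (stride + 1)] = 0;  // filter type 0
    unsigned char* row = raw.data() + y * (stride + 1) + 1;
    for (size_t i = 0; i < (size_t)width * channels; ++i) {
      int v = pixels[k++];
      if (bitdepth == 8) {
        row[i] = (unsigned char)v;
      } else {
        row[2 * i] = (unsigned char)((v >> 8) & 0xff);
        row[2 * i + 1] = (unsigned char)(v & 0xff);
      }
    }
  }
  uLongf comp_len = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(comp_len);
  if (compress2(comp.data(), &comp_len, raw.data(), (uLong)raw.size(), 6) != Z_OK)
    stop("zlib compression failed");

  std::vector<unsigned char> out;
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  out.insert(out.end(), sig, sig + 8);
  unsigned char ihdr[13];
  ihdr[0] = (width >> 24) & 0xff; ihdr[1] = (width >> 16) & 0xff;
  ihdr[2] = (width >> 8) & 0xff;  ihdr[3] = width & 0xff;
  ihdr[4] = (height >> 24) & 0xff; ihdr[5] = (height >> 16) & 0xff;
  ihdr[6] = (height >> 8) & 0xff;  ihdr[7] = height & 0xff;
  ihdr[8] = (unsigned char)bitdepth;
  ihdr[9] = (channels == 3) ? 2 : 0;  // colour type: truecolour / greyscale
  ihdr[10] = 0; ihdr[11] = 0; ihdr[12] = 0;
  push_chunk(out, "IHDR", ihdr, 13);
  push_chunk(out, "IDAT", comp.data(), comp_len);
  push_chunk(out, "IEND", NULL, 0);
  return RawVector(out.begin(), out.end());
}

static inline int paeth(int a, int b, int c) {
  int p = a + b - c, pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// [[Rcpp::export(name = ".png_decode")]]
List png_decode(RawVector bytes) {
  const unsigned char* p = RAW(bytes);
  size_t n = bytes.size();
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  if (n < 8 || std::memcmp(p, sig, 8) != 0) stop("not a PNG file");
  size_t pos = 8;
  int width = 0, height = 0, bitdepth = 0, colortype = -1;
  std::vector<unsigned char> idat;
  while (pos + 8 <= n) {
    uint32_t len = ((uint32_t)p[pos] << 24) | (p[pos + 1] << 16) |
                   (p[pos + 2] << 8) | p[pos + 3];
    const char* type = (const char*)p + pos + 4;
    const unsigned char* data = p + pos + 8;
    if (pos + 12 + len > n) stop("truncated PNG chunk");
    if (std::memcmp(type, "IHDR", 4) == 0) {
      width = (data[0] << 24) | (data[1] << 16) | (data[2] << 8) | data[3];
      height = (data[4] << 24) | (data[5] << 16) | (data[6] << 8) | data[7];
      bitdepth = data[8]; colortype = data[9];
      if (data[12] != 0) stop("interlaced PNG not supported");
    } else if (std::memcmp(type, "IDAT", 4) == 0) {
      idat.insert(idat.end(), data, data + len);
    } else if (std::memcmp(type, "IEND", 4) == 0) {
      break;
    }
    pos += 12 + len;
  }
  int channels;
  if (colortype == 2 && bitdepth == 8) channels = 3;
  else if (colortype == 0 && (bitdepth == 8 || bitdepth == 16)) channels = 1;
  else stop("unsupported PNG colour type %d / bit depth %d", colortype, bitdepth);
  const int bpp = channels * bitdepth / 8;
  const size_t stride = (size_t)width * bpp;
  uLongf raw_len = (uLong)((stride + 1) * height);
  std::vector<unsigned char> raw(raw_len);
  if (uncompress(raw.data(), &raw_len, idat.data(), (uLong)idat.size()) != Z_OK ||
      raw_len != (stride + 1) * (size_t)height)
    stop("corrupt PNG image data");

  // undo scanline filtering in place
  std::vector<unsigned char> prev(stride, 0);
  for (int y = 0; y < height; ++y) {
    unsigned char f = raw[y * (stride + 1)];
    unsigned char* row = raw.data() + y * (stride + 1) + 1;
    for (size_t i = 0; i < stride; ++i) {
      int a = (i >= (size_t)bpp) ? row[i - bpp] : 0;
      int b = prev[i];
      int c = (i >= (size_t)bpp) ? prev[i - bpp] : 0;
      int add;
      switch (f) {
        case 0: add = 0; break;
        case 1: add = a; break;
        case 2: add = b; break;
        case 3: add = (a + b) / 2; break;
        case 4: add = paeth(a, b, c); break;
        default: stop("unknown PNG filter %d", (int)f);
      }
      row[i] = (unsigned char)((row[i] + add) & 0xff);
    }
    std::memcpy(prev.data(), row, stride);
  }
  IntegerVector out((R_xlen_t)height * width * channels);
  size_t k = 0;
  for (int y = 0; y < height; ++y) {
    const unsigned char* row = raw.data() + y * (stride + 1) + 1;
    for (size_t i = 0; i < (size_t)width * channels; ++i) {
      out[k++] = (bitdepth == 8) ? row[i] : ((row[2 * i] << 8) | row[2 * i + 1]);
    }
  }
  return List::create(_["pixels"] = out, _["height"] = height,
                      _["width"] = width, _["channels"] = channels,
                      _["bitdepth"] = bitdepth);
}

// [[Rcpp::export(name = ".crc32_raw")]]
double crc32_raw(RawVector bytes) {
  uLong crc = crc32(0L, Z_NULL, 0);
  if (bytes.size() > 0) crc = crc32(crc, RAW(bytes), (uInt)bytes.size());
  return (double)crc;
}
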