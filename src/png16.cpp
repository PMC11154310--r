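#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <vector>
#include <cstring>

using namespace Rcpp;

// Minimal 16-bit grayscale PNG writer (the png package reads 16-bit but only
// writes 8-bit). Depth images are stored as big-endian uint16 millimeters.

namespace {

void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

void write_chunk(FILE* f, const char* type, const std::vector<unsigned char>& data) {
  std::vector<unsigned char> hdr;
  put_u32(hdr, (uint32_t)data.size());
  fwrite(hdr.data(), 1, 4, f);
  fwrite(type, 1, 4, f);
  if (!data.empty()) fwrite(data.data(), 1, data.size(), f);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, (const Bytef*)type, 4);
  if (!data.empty()) crc = crc32(crc, data.data(), (uInt)data.size());
  std::vector<unsigned char> tail;
  put_u32(tail, (uint32_t)crc);
  fwrite(tail.data(), 1, 4, f);
}

}  // namespace

// [[Rcpp::export]]
void cpp_png16_write(std::string path, IntegerMatrix img) {
  int h = img.nrow(), w = img.ncol();
  // raw scanlines: filter byte 0 + big-endian uint16 per pixel
  std::vector<unsigned char> raw((size_t)h * (1 + 2 * (size_t)w));
  size_t p = 0;
  for (int i = 0; i < h; ++i) {
    raw[p++] = 0;
    for (int j = 0; j < w; ++j) {
      int v = img(i, j);
      if (v < 0) v = 0;
      if (v > 65535) v = 65535;
      raw[p++] = (v >> 8) & 0xff;
      raw[p++] = v & 0xff;
    }
  }
  uLongf zlen = compressBound((uLong)raw.size());
  std::vector<unsigned char> z(zlen);
  if (compress2(z.data(), &zlen, raw.data(), (uLong)raw.size(), 6) != Z_OK)
    stop("PNG deflate failed");
  z.resize(zlen);

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  static const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  fwrite(sig, 1, 8, f);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, (uint32_t)w);
  put_u32(ihdr, (uint32_t)h);
  ihdr.push_back(16);  // bit depth
  ihdr.push_back(0);   // grayscale
  ihdr.push_back(0);
  ihdr.push_back(0);
  ihdr.push_back(0);
  write_chunk(f, "IHDR", ihdr);
  write_chunk(f, "IDAT", z);
  write_chunk(f, "IEND", std::vector<unsigned char>());
  std::fclose(f);
}
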