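// Thin zlib bindings: raw DEFLATE streams and crc32.  All BGZF framing
// lives in R; only the codec primitives that base R does not expose
// (compression level, raw windowBits, crc32) come from here.
#include <Rcpp.h>
#include <zlib.h>
#include <vector>
#include <cstring>

using namespace Rcpp;

// [[Rcpp::export(name = ".zlib_deflate_raw")]]
RawVector zlib_deflate_raw(RawVector data, int level) {
    if (level < 0 || level > 9) stop("compression level must be in 0..9");
    z_stream s;
    std::memset(&s, 0, sizeof(s));
    // windowBits = -15: raw deflate, no zlib/gzip wrapper
    if (deflateInit2(&s, level, Z_DEFLATED, -15, 8, Z_DEFAULT_STRATEGY) != Z_OK)
        stop("deflateInit2 failed");
    uLong bound = deflateBound(&s, (uLong)data.size());
    std::vector<Bytef> out(bound ? bound : 16);
    s.next_in = (Bytef*)(data.size() ? RAW(data) : (Rbyte*)"");
    s.avail_in = (uInt)data.size();
    s.next_out = out.data();
    s.avail_out = (uInt)out.size();
    int ret = deflate(&s, Z_FINISH);
    uLong n = s.total_out;
    deflateEnd(&s);
    if (ret != Z_STREAM_END) stop("deflate did not reach stream end");
    RawVector res(n);
    if (n) std::memcpy(RAW(res), out.data(), n);
    return res;
}

// [[Rcpp::export(name = ".zlib_inflate_raw")]]
RawVector zlib_inflate_raw(RawVector data, double expected_size) {
    if (expected_size < 0 || expected_size > 4294967295.0)
        stop("bad expected size");
    size_t want = (size_t)expected_size;
    z_stream s;
    std::memset(&s, 0, sizeof(s));
    if (inflateInit2(&s, -15) != Z_OK) stop("inflateInit2 failed");
    std::vector<Bytef> out(want ? want : 1);
    s.next_in = (Bytef*)(data.size() ? RAW(data) : (Rbyte*)"");
    s.avail_in = (uInt)data.size();
    s.next_out = out.data();
    s.avail_out = (uInt)(want ? want : 1);
    int ret = inflate(&s, Z_FINISH);
    uLong n = s.total_out;
    inflateEnd(&s);
    if (!(ret == Z_STREAM_END || (ret == Z_BUF_ERROR && n == want)))
        stop("inflate failed: corrupt deflate stream");
    if (n != want) stop("inflate: size mismatch");
    RawVector res(n);
    if (n) std::memcpy(RAW(res), out.data(), n);
    return res;
}

// [[Rcpp::export(name = ".zlib_crc32")]]
double zlib_crc32_(RawVector data) {
    uLong c = crc32(0L, Z_NULL, 0);
    if (data.size())
        c = crc32(c, RAW(data), (uInt)data.size());
    return (double)c;
}
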