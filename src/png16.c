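/* Minimal 16-bit grayscale PNG writer for integer label masks.
 *
 * The CRAN png package and EBImage both write 8-bit PNG only, which cannot
 * hold more than 255 object IDs.  This encoder emits a single IDAT chunk
 * (zlib, filter type 0 on every scanline) with 16-bit big-endian samples.
 */

#include <R.h>
#include <Rinternals.h>
#include <stdio.h>
#include <stdlib.h>
#include <string.h>
#include <zlib.h>

static void put_be32(unsigned char *p, unsigned long v)
{
    p[0] = (unsigned char)((v >> 24) & 0xff);
    p[1] = (unsigned char)((v >> 16) & 0xff);
    p[2] = (unsigned char)((v >> 8) & 0xff);
    p[3] = (unsigned char)(v & 0xff);
}

static int write_chunk(FILE *f, const char type[4],
                       const unsigned char *data, size_t len)
{
    unsigned char hdr[8], crcbuf[4];
    unsigned long crc;

    put_be32(hdr, (unsigned long)len);
    memcpy(hdr + 4, type, 4);
    if (fwrite(hdr, 1, 8, f) != 8) return 0;
    if (len > 0 && fwrite(data, 1, len, f) != len) return 0;
    crc = crc32(0L, Z_NULL, 0);
    crc = crc32(crc, (const unsigned char *)type, 4);
    if (len > 0) crc = crc32(crc, data, (uInt)len);
    put_be32(crcbuf, crc);
    return fwrite(crcbuf, 1, 4, f) == 4;
}

/* labels: integer vector, column-major h x w matrix; values in [0, 65535] */
SEXP cometrics_write_png16(SEXP labels, SEXP dims, SEXP path)
{
    const int *lab = INTEGER(labels);
    int h = INTEGER(dims)[0], w = INTEGER(dims)[1];
    const char *fname = CHAR(STRING_ELT(path, 0));
    size_t stride = (size_t)w * 2 + 1;      /* filter byte + samples */
    size_t rawlen = stride * (size_t)h;
    unsigned char *raw, *comp, ihdr[13];
    uLongf complen;
    FILE *f;
    int r, c, ok = 1;
    static const unsigned char sig[8] =
        {137, 80, 78, 71, 13, 10, 26, 10};

    raw = (unsigned char *)malloc(rawlen);
    if (!raw) error("cannot allocate PNG scanline buffer");
    for (r = 0; r < h; r++) {
        unsigned char *row = raw + stride * (size_t)r;
        row[0] = 0;                          /* filter: none */
        for (c = 0; c < w; c++) {
            int v = lab[(size_t)c * h + r];
            row[1 + 2 * c] = (unsigned char)((v >> 8) & 0xff);
            row[2 + 2 * c] = (unsigned char)(v & 0xff);
        }
    }

    complen = compressBound((uLong)rawlen);
    comp = (unsigned char *)malloc(complen);
    if (!comp) { free(raw); error("cannot allocate PNG buffer"); }
    if (compress2(comp, &complen, raw, (uLong)rawlen, 6) != Z_OK) {
        free(raw); free(comp);
        error("zlib compression failed");
    }
    free(raw);

    f = fopen(fname, "wb");
    if (!f) { free(comp); error("cannot open '%s' for writing", fname); }

    ok = fwrite(sig, 1, 8, f) == 8;
    put_be32(ihdr, (unsigned long)w);
    put_be32(ihdr + 4, (unsigned long)h);
    ihdr[8] = 16;  /* bit depth */
    ihdr[9] = 0;   /* grayscale */
    ihdr[10] = ihdr[11] = ihdr[12] = 0;
    ok = ok && write_chunk(f, "IHDR", ihdr, 13);
    ok = ok && write_chunk(f, "IDAT", comp, (size_t)complen);
    ok = ok && write_chunk(f, "IEND", NULL, 0);
    free(comp);
    if (fclose(f) != 0) ok = 0;
    if (!ok) error("error while writing '%s'", fname);
    return R_NilValue;
}
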