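// generated: real spherical harmonics Y_lm and gradients, l<=4
// layout: idx = l*l + (m+l); Y[idx], dY[3*idx + {0,1,2}] = d/d{x,y,z}
static void ylm_grad(double x, double y, double z, double* Y, double* dY) {
  const double x0 = pow(M_PI, -1.0/2.0);
  const double x1 = (1.0/2.0)*x0;
  const double x2 = x1*y;
  const double x3 = sqrt(3);
  const double x4 = pow(z, 2);
  const double x5 = pow(x, 2);
  const double x6 = pow(y, 2);
  const double x7 = x5 + x6;
  const double x8 = x4 + x7;
  const double x9 = x3/sqrt(x8);
  const double x10 = x1*x9;
  const double x11 = 1.0/x8;
  const double x12 = sqrt(15);
  const double x13 = x11*x12;
  const double x14 = x13*x2;
  const double x15 = sqrt(5);
  const double x16 = 2*x4;
  const double x17 = -x16;
  const double x18 = x11*(x17 + x7);
  const double x19 = (1.0/4.0)*x0;
  const double x20 = x*x1;
  const double x21 = x20*z;
  const double x22 = -x6;
  const double x23 = x22 + x5;
  const double x24 = x11*x23;
  const double x25 = pow(x8, -3.0/2.0);
  const double x26 = (1.0/8.0)*x25;
  const double x27 = x0*y;
  const double x28 = 3*x5;
  const double x29 = x22 + x28;
  const double x30 = sqrt(70);
  const double x31 = x29*x30;
  const double x32 = x27*x31;
  const double x33 = x25*z;
  const double x34 = x*x33;
  const double x35 = sqrt(105);
  const double x36 = x2*x35;
  const double x37 = 4*x4;
  const double x38 = -x37;
  const double x39 = x38 + x7;
  const double x40 = sqrt(42);
  const double x41 = x26*x40;
  const double x42 = x27*x41;
  const double x43 = 3*x6;
  const double x44 = x28 + x43;
  const double x45 = x17 + x44;
  const double x46 = sqrt(7);
  const double x47 = x19*x25;
  const double x48 = x46*x47;
  const double x49 = x0*x41;
  const double x50 = x23*z;
  const double x51 = x35*x47;
  const double x52 = x0*x30;
  const double x53 = x26*x52;
  const double x54 = -x43;
  const double x55 = x5 + x54;
  const double x56 = x*x55;
  const double x57 = pow(x8, 2);
  const double x58 = 1.0/x57;
  const double x59 = x0*x58;
  const double x60 = x*x59;
  const double x61 = x60*y;
  const double x62 = sqrt(35);
  const double x63 = (3.0/4.0)*x62;
  const double x64 = x59*y;
  const double x65 = (3.0/8.0)*x64;
  const double x66 = x65*z;
  const double x67 = 6*x4;
  const double x68 = -x67;
  const double x69 = x68 + x7;
  const double x70 = pow(z, 4);
  const double x71 = x5*x6;
  const double x72 = pow(x, 4);
  const double x73 = pow(y, 4);
  const double x74 = x72 + x73;
  const double x75 = 1.0/(x16*x5 + x16*x6 + x70 + 2*x71 + x74);
  const double x76 = x0*x15;
  const double x77 = x75*x76;
  const double x78 = x38 + x44;
  const double x79 = sqrt(10);
  const double x80 = x78*x79;
  const double x81 = -30*x4*x8 + 3*x57 + 35*x70;
  const double x82 = (3.0/16.0)*x59;
  const double x83 = (3.0/8.0)*x60;
  const double x84 = x83*z;
  const double x85 = -x5*x67 + x6*x67 + x72 - x73;
  const double x86 = x30*x55;
  const double x87 = -6*x71 + x74;
  const double x88 = x62*x87;
  const double x89 = x25*x3;
  const double x90 = x2*x89;
  const double x91 = -x*x90;
  const double x92 = x11*x6;
  const double x93 = -x90*z;
  const double x94 = -x21*x89;
  const double x95 = x11*x4;
  const double x96 = x11*x5;
  const double x97 = 1.0/2.0 - x96;
  const double x98 = x13*x27;
  const double x99 = x0*x13;
  const double x100 = x99*(1.0/2.0 - x92);
  const double x101 = x61*z;
  const double x102 = -x101*x12;
  const double x103 = 1.0/2.0 - x95;
  const double x104 = x11*x15*(x18 - 1);
  const double x105 = x11*x29;
  const double x106 = x*x25;
  const double x107 = (3.0/8.0)*x106*x27*x30;
  const double x108 = -x28;
  const double x109 = x108 + x43;
  const double x110 = (3.0/8.0)*z/pow(x8, 5.0/2.0);
  const double x111 = x11*x28;
  const double x112 = 1 - 3*x95;
  const double x113 = x11*x39;
  const double x114 = x*x42*(3*x113 - 2);
  const double x115 = x38 + x43;
  const double x116 = x27*x33;
  const double x117 = x40*((3.0/8.0)*x113 + 1);
  const double x118 = x0*x34;
  const double x119 = (3.0/4.0)*x46*(x11*x45 - 2);
  const double x120 = 3*x24;
  const double x121 = x51*z;
  const double x122 = x11*x55;
  const double x123 = -3.0/4.0*x5;
  const double x124 = (1.0/4.0)*x6;
  const double x125 = 3*x62;
  const double x126 = (1.0/4.0)*x5;
  const double x127 = (3.0/4.0)*x6;
  const double x128 = pow(x8, -3);
  const double x129 = (3.0/4.0)*x101;
  const double x130 = x129*x30;
  const double x131 = x59*z;
  const double x132 = (3.0/8.0)*x131;
  const double x133 = x132*x30;
  const double x134 = -x11*x37 + 1;
  const double x135 = x75*x8;
  const double x136 = x135*x69;
  const double x137 = 3*x77;
  const double x138 = x137*y;
  const double x139 = x129*x79*(2*x11*x78 - 3);
  const double x140 = x132*x79;
  const double x141 = -12*x4 + x44;
  const double x142 = x79*(4*x11*x4*x78 - x141);
  const double x143 = (3.0/4.0)*x11*x81 - 3.0/4.0*x141;
  const double x144 = -x5;
  const double x145 = 3*x4;
  const double x146 = x135*x85;
  const double x147 = (3.0/2.0)*x77;
  const double x148 = x11*x87;
  Y[0] = x1;
  Y[1] = x2*x9;
  Y[2] = x10*z;
  Y[3] = x*x10;
  Y[4] = x*x14;
  Y[5] = x14*z;
  Y[6] = -x15*x18*x19;
  Y[7] = x13*x21;
  Y[8] = x12*x19*x24;
  Y[9] = x26*x32;
  Y[10] = x34*x36;
  Y[11] = -x39*x42;
  Y[12] = -x45*x48*z;
  Y[13] = -x*x39*x49;
  Y[14] = x50*x51;
  Y[15] = x53*x56;
  Y[16] = x23*x61*x63;
  Y[17] = x31*x66;
  Y[18] = -3.0/4.0*x*x69*x77*y;
  Y[19] = -x66*x80;
  Y[20] = x81*x82;
  Y[21] = -x80*x84;
  Y[22] = -3.0/8.0*x77*x85;
  Y[23] = x84*x86;
  Y[24] = x82*x88;
  dY[0] = 0;
  dY[1] = 0;
  dY[2] = 0;
  dY[3] = x91;
  dY[4] = x10*(1 - x92);
  dY[5] = x93;
  dY[6] = x94;
  dY[7] = x93;
  dY[8] = x10*(1 - x95);
  dY[9] = x10*(1 - x96);
  dY[10] = x91;
  dY[11] = x94;
  dY[12] = x97*x98;
  dY[13] = x*x100;
  dY[14] = x102;
  dY[15] = x102;
  dY[16] = x100*z;
  dY[17] = x103*x98;
  dY[18] = x104*x20;
  dY[19] = x104*x2;
  dY[20] = x11*x76*z*((1.0/2.0)*x18 + 1);
  dY[21] = x97*x99*z;
  dY[22] = x102;
  dY[23] = x*x103*x99;
  dY[24] = x13*x20*(1 - x24);
  dY[25] = -x14*(x24 + 1);
  dY[26] = -x1*x12*x50*x58;
  dY[27] = x107*(2 - x105);
  dY[28] = x53*(-x105*x43 - x109);
  dY[29] = -x110*x32;
  dY[30] = x33*x36*(1 - x111);
  dY[31] = x21*x25*x35*(-x11*x43 + 1);
  dY[32] = x106*x112*x36;
  dY[33] = x114;
  dY[34] = x49*(3*x11*x39*x6 - x115 - x5);
  dY[35] = x116*x117;
  dY[36] = x118*x119;
  dY[37] = x116*x119;
  dY[38] = x48*(3*x11*x4*x45 - x44 - x68);
  dY[39] = x49*(x108 + x111*x39 + x22 + x37);
  dY[40] = x114;
  dY[41] = x117*x118;
  dY[42] = x*x121*(2 - x120);
  dY[43] = -x121*y*(x120 + 2);
  dY[44] = x112*x23*x51;
  dY[45] = x53*(-x109 - x122*x28);
  dY[46] = -x107*(x122 + 2);
  dY[47] = -x110*x52*x56;
  dY[48] = x125*x64*(-x123 - x124 - x23*x96);
  dY[49] = x125*x60*(x126 - x127 - x23*x92);
  dY[50] = -x*x125*x128*x27*x50;
  dY[51] = x130*(3 - 2*x105);
  dY[52] = x133*(-x109 - 4*x29*x92);
  dY[53] = x134*x31*x65;
  dY[54] = x138*(x123 - x124 + x136*x5 + (3.0/2.0)*x4);
  dY[55] = x*x137*(-x126 - x127 + (3.0/2.0)*x4 + x6*x69*x75*x8);
  dY[56] = x*x138*z*(x136 + 3);
  dY[57] = x139;
  dY[58] = x140*(4*x11*x6*x78 - x28 - x38 - 9*x6);
  dY[59] = x142*x65;
  dY[60] = -x143*x60;
  dY[61] = -x143*x64;
  dY[62] = 3*x131*(-1.0/4.0*x11*x81 - x45);
  dY[63] = x140*(4*x11*x5*x78 - x115 - 9*x5);
  dY[64] = x139;
  dY[65] = x142*x83;
  dY[66] = x*x147*(x144 + x145 + x146);
  dY[67] = x147*y*(-x145 + x146 + x6);
  dY[68] = x147*z*(x146 + x28 + x54);
  dY[69] = x133*(-x109 - 4*x55*x96);
  dY[70] = -x130*(2*x122 + 3);
  dY[71] = x134*x83*x86;
  dY[72] = x60*x63*(-x144 - x148 - x43);
  dY[73] = -x63*x64*(x148 + x29);
  dY[74] = -3.0/4.0*x0*x128*x88*z;
}
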