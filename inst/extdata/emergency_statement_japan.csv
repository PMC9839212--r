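prefecture_en,emergency_start,emergency_end,times
Chiba,2020-04-07,2020-05-25,1
Fukuoka,2020-04-07,2020-05-14,1
Hyogo,2020-04-07,2020-05-21,1
Kanagawa,2020-04-07,2020-05-25,1
Osaka,2020-04-07,2020-05-21,1
Saitama,2020-04-07,2020-05-25,1
Tokyo,2020-04-07,2020-05-25,1
Aichi,2020-04-16,2020-05-14,1
Akita,2020-04-16,2020-05-14,1
Aomori,2020-04-16,2020-05-14,1
Ehime,2020-04-16,2020-05-14,1
Fukui,2020-04-16,2020-05-14,1
Fukushima,2020-04-16,2020-05-14,1
Gifu,2020-04-16,2020-05-14,1
Gunma,2020-04-16,2020-05-14,1
Hiroshima,2020-04-16,2020-05-14,1
Hokkaido,2020-04-16,2020-05-25,1
Ibaraki,2020-04-16,2020-05-14,1
Ishikawa,2020-04-16,2020-05-14,1
Iwate,2020-04-16,2020-05-14,1
Kagawa,2020-04-16,2020-05-14,1
Kagoshima,2020-04-16,2020-05-14,1
Kochi,2020-04-16,2020-05-14,1
Kumamoto,2020-04-16,2020-05-14,1
Kyoto,2020-04-16,2020-05-21,1
Mie,2020-04-16,2020-05-14,1
Miyagi,2020-04-16,2020-05-14,1
Miyazaki,2020-04-16,2020-05-14,1
Nagano,2020-04-16,2020-05-14,1
Nagasaki,2020-04-16,2020-05-14,1
Nara,2020-04-16,2020-05-14,1
Niigata,2020-04-16,2020-05-14,1
Oita,2020-04-16,2020-05-14,1
Okayama,2020-04-16,2020-05-14,1
Okinawa,2020-04-16,2020-05-14,1
Saga,2020-04-16,2020-05-14,1
Shiga,2020-04-16,2020-05-14,1
Shimane,2020-04-16,2020-05-14,1
Shizuoka,2020-04-16,2020-05-14,1
Tochigi,2020-04-16,2020-05-14,1
Tokushima,2020-04-16,2020-05-14,1
Tottori,2020-04-16,2020-05-14,1
Toyama,2020-04-16,2020-05-14,1
Wakayama,2020-04-16,2020-05-14,1
Yamagata,2020-04-16,2020-05-14,1
Yamaguchi,2020-04-16,2020-05-14,1
Yamanashi,2020-04-16,2020-05-14,1
Chiba,2021-01-08,2021-03-21,2
Kanagawa,2021-01-08,2021-03-21,2
Saitama,2021-01-08,2021-03-21,2
Tokyo,2021-01-08,2021-03-21,2
Aichi,2021-01-14,2021-02-28,2
Fukuoka,2021-01-14,2021-02-28,2
Gifu,2021-01-14,2021-02-28,2
Hyogo,2021-01-14,2021-02-28,2
Kyoto,2021-01-14,2021-02-28,2
Osaka,2021-01-14,2021-02-28,2
Tochigi,2021-01-14,2021-02-07,2
Hyogo,2021-04-25,2021-06-20,3
Kyoto,2021-04-25,2021-06-20,3
Osaka,2021-04-25,2021-06-20,3
Tokyo,2021-04-25,2021-06-20,3
Aichi,2021-05-12,2021-06-20,3
Fukuoka,2021-05-12,2021-06-20,3
Hiroshima,2021-05-16,2021-06-20,2
Hokkaido,2021-05-16,2021-06-20,2
Okayama,2021-05-16,2021-06-20,2
Okinawa,2021-05-23,2021-09-30,2
Tokyo,2021-07-12,2021-09-30,4
Chiba,2021-08-02,2021-09-30,3
Kanagawa,2021-08-02,2021-09-30,3
Osaka,2021-08-02,2021-09-30,4
Saitama,2021-08-02,2021-09-30,3
Fukuoka,2021-08-20,2021-09-30,4
Gunma,2021-08-20,2021-09-30,2
Hyogo,2021-08-20,2021-09-30,4
Ibaraki,2021-08-20,2021-09-30,2
Kyoto,2021-08-20,2021-09-30,4
Shizuoka,2021-08-20,2021-09-30,2
Tochigi,2021-08-20,2021-09-30,3
Aichi,2021-08-27,2021-09-30,4
Gifu,2021-08-27,2021-09-30,3
Hiroshima,2021-08-27,2021-09-30,3
Hokkaido,2021-08-27,2021-09-30,3
Mie,2021-08-27,2021-09-30,2
Miyagi,2021-08-27,2021-09-12,2
Okayama,2021-08-27,2021-09-12,3
Shiga,2021-08-27,2021-09-30,2
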